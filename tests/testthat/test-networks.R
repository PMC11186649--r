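test_that("generator honors the two-channel shape contract", {
  set.seed(1)
  g2 <- build_generator(generator_spec(out_channels = 2, depth = 3,
                                       base_filters = 2, dropout_rate = 0.2))
  x <- rand_arr(c(16, 16, 16), seed = 2, sd = 0.5)
  out <- apply_generator(g2, volume(x))
  expect_identical(dim(out$translation$data), dim(x))
  expect_identical(dim(out$log_sigma), dim(x))
  expect_true(all(out$translation$data >= -1 & out$translation$data <= 1))

  g1 <- build_generator(generator_spec(out_channels = 1, depth = 2,
                                       base_filters = 2))
  out1 <- apply_generator(g1, x)
  expect_null(out1$log_sigma)
  # spatial dims must divide 2^(depth-1)
  expect_error(apply_generator(g2, rand_arr(c(10, 16, 16), seed = 3)),
               "divisible")
})

test_that("dropout controls inference stochasticity", {
  x <- rand_arr(c(8, 8, 8), seed = 4, sd = 0.5)
  set.seed(5)
  g0 <- build_generator(generator_spec(depth = 2, base_filters = 2,
                                       dropout_rate = 0))
  a <- apply_generator(g0, x, dropout = TRUE)
  b <- apply_generator(g0, x, dropout = TRUE)
  expect_identical(a$translation$data, b$translation$data)

  set.seed(6)
  gd <- build_generator(generator_spec(depth = 2, base_filters = 2,
                                       dropout_rate = 0.3))
  set.seed(7)
  a <- apply_generator(gd, x, dropout = TRUE)
  b <- apply_generator(gd, x, dropout = TRUE)
  expect_false(identical(a$translation$data, b$translation$data))
  # dropout off: deterministic
  c1 <- apply_generator(gd, x, dropout = FALSE)
  c2 <- apply_generator(gd, x, dropout = FALSE)
  expect_identical(c1$translation$data, c2$translation$data)
})

test_that("discriminator returns a finite multi-patch score grid", {
  set.seed(8)
  d3 <- build_discriminator(discriminator_spec(n_layers = 3, base_filters = 2))
  x <- rand_arr(c(32, 32, 32), seed = 9, sd = 0.5)
  s <- apply_discriminator(d3, x)
  expect_true(all(dim(s) > 1))            # grid of patch scores, not a scalar
  expect_identical(dim(s), c(4L, 4L, 4L))
  expect_true(all(is.finite(s)) && all(s > 0 & s < 1))
  expect_identical(apply_discriminator(d3, x), s)
  expect_error(apply_discriminator(d3, rand_arr(c(4, 4, 4), seed = 1)),
               "divisible")
})

test_that("backpropagation matches finite differences", {
  ns <- asNamespace("ucycle")
  fd <- function(f, x, h = 1e-6) {
    g <- x * 0
    for (i in seq_along(x)) {
      xp <- x; xp[i] <- x[i] + h
      xm <- x; xm[i] <- x[i] - h
      g[i] <- (f(xp) - f(xm)) / (2 * h)
    }
    g
  }
  relerr <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))

  set.seed(10)
  gen <- build_generator(generator_spec(out_channels = 2, depth = 2,
                                        base_filters = 2, dropout_rate = 0))
  x <- rand_arr(c(8, 8, 8), seed = 11, sd = 0.5)
  wt <- rand_arr(c(8, 8, 8), seed = 12)
  ws <- rand_arr(c(8, 8, 8), seed = 13)
  loss <- function(g, xx) {
    o <- ns$generator_forward(g, xx, FALSE, FALSE)
    sum(o$translation * wt) + sum(o$log_sigma * ws)
  }
  fwd <- ns$generator_forward(gen, x, FALSE, TRUE)
  bw <- ns$generator_backward(gen, fwd$cache, wt, ws)
  expect_lt(relerr(bw$dx, fd(function(xx) loss(gen, xx), x)), 1e-6)
  for (nm in c("enc1_conv", "down1_conv", "dec1_conv", "head_conv")) {
    gn <- fd(function(v) { g <- gen; g$params[[nm]]$W <- v; loss(g, x) },
             gen$params[[nm]]$W)
    expect_lt(relerr(bw$grads[[nm]]$W, gn), 1e-5)
  }

  set.seed(14)
  disc <- build_discriminator(discriminator_spec(n_layers = 2, base_filters = 2))
  wsc <- rand_arr(c(2, 2, 2), seed = 15)
  dloss <- function(d, xx) sum(ns$discriminator_forward(d, xx, FALSE)$scores * wsc)
  fwd <- ns$discriminator_forward(disc, x, TRUE)
  bw <- ns$discriminator_backward(disc, fwd$cache, wsc)
  expect_lt(relerr(bw$dx, fd(function(xx) dloss(disc, xx), x)), 1e-6)
  gn <- fd(function(v) { d <- disc; d$params$d1_conv$W <- v; dloss(d, x) },
           disc$params$d1_conv$W)
  expect_lt(relerr(bw$grads$d1_conv$W, gn), 1e-5)

  # loss-side gradients: gradient-correlation prior and aleatoric terms
  a <- rand_arr(c(4, 4, 4), seed = 16)
  b <- rand_arr(c(4, 4, 4), seed = 17)
  expect_lt(relerr(ns$gradient_correlation_grad_b(a, b),
                   fd(function(bb) gradient_correlation(a, bb), b)), 1e-6)
  r <- rand_arr(c(3, 3, 3), seed = 18)
  s <- rand_arr(c(3, 3, 3), seed = 19)
  z <- array(0, c(3, 3, 3))
  gr <- ns$aleatoric_term_grads(a[1:3, 1:3, 1:3], r, s)
  o <- a[1:3, 1:3, 1:3]
  expect_lt(relerr(gr$d_rec,
                   fd(function(rr) aleatoric_cycle_loss(o, rr, s, z, z, z), r)), 1e-6)
  expect_lt(relerr(gr$d_log_sigma,
                   fd(function(ss) aleatoric_cycle_loss(o, r, ss, z, z, z), s)), 1e-6)
})

test_that("invalid architecture specifications are rejected", {
  expect_error(generator_spec(out_channels = 3), "1 or 2")
  expect_error(generator_spec(dropout_rate = 1), "dropout_rate")
  expect_error(discriminator_spec(n_layers = 0), "n_layers")
})
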