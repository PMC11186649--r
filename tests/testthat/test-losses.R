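# Brute-force oracles written as explicit index loops, independent of the
# package's vectorized implementations.

oracle_fd <- function(v) {
  d <- dim(v)
  g <- list(gx = array(0, d), gy = array(0, d), gz = array(0, d))
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    g$gx[i, j, k] <- v[min(i + 1, d[1]), j, k] - v[min(i + 1, d[1]) - 1, j, k]
    g$gy[i, j, k] <- v[i, min(j + 1, d[2]), k] - v[i, min(j + 1, d[2]) - 1, k]
    g$gz[i, j, k] <- v[i, j, min(k + 1, d[3])] - v[i, j, min(k + 1, d[3]) - 1]
  }
  g
}

oracle_ncc <- function(a, b) {
  ma <- 0; mb <- 0; n <- length(a)
  for (i in seq_along(a)) { ma <- ma + a[i] / n; mb <- mb + b[i] / n }
  num <- 0; da <- 0; db <- 0
  for (i in seq_along(a)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / (sqrt(da) * sqrt(db))
}

test_that("spatial gradients match an index-by-index oracle", {
  v <- rand_arr(c(4, 4, 4), seed = 31)
  g <- spatial_gradients(v)
  o <- oracle_fd(v)
  expect_equal(g$gx, o$gx, tolerance = 1e-14)
  expect_equal(g$gy, o$gy, tolerance = 1e-14)
  expect_equal(g$gz, o$gz, tolerance = 1e-14)
  # degenerate and closed-form cases
  expect_true(all(spatial_gradients(array(2, c(3, 3, 3)))$gx == 0))
  ramp <- array(rep(1:4, 16), c(4, 4, 4))
  gr <- spatial_gradients(ramp)
  expect_true(all(gr$gx == 1) && all(gr$gy == 0) && all(gr$gz == 0))
  expect_error(spatial_gradients(array(0, c(1, 3, 3))), ">= 2")
})

test_that("ncc and gradient_correlation match brute-force evaluation", {
  set.seed(99)
  for (rep in 1:100) {
    d <- sample(2:4, 3, replace = TRUE)
    a <- array(stats::rnorm(prod(d)), d)
    b <- array(stats::rnorm(prod(d)), d)
    expect_equal(ncc(a, b), oracle_ncc(as.vector(a), as.vector(b)),
                 tolerance = 1e-10)
    ga <- oracle_fd(a); gb <- oracle_fd(b)
    oracle_gc <- (oracle_ncc(as.vector(ga$gx), as.vector(gb$gx)) +
                    oracle_ncc(as.vector(ga$gy), as.vector(gb$gy)) +
                    oracle_ncc(as.vector(ga$gz), as.vector(gb$gz))) / 3
    expect_equal(gradient_correlation(a, b), oracle_gc, tolerance = 1e-10)
  }
})

test_that("gradient correlation identities and invariances hold", {
  a <- rand_arr(c(4, 4, 4), seed = 5)
  expect_equal(gradient_correlation(a, a), 1, tolerance = 1e-12)
  expect_equal(gradient_correlation(a, 0.7 - a), -1, tolerance = 1e-12)
  g <- spatial_gradients(a)
  expect_equal(ncc(g$gx, g$gx), 1, tolerance = 1e-12)
  expect_equal(ncc(g$gx, -g$gx), -1, tolerance = 1e-12)
  # shift invariance and range
  b <- rand_arr(c(4, 4, 4), seed = 6)
  expect_equal(gradient_correlation(a + 3, b - 1), gradient_correlation(a, b),
               tolerance = 1e-12)
  set.seed(7)
  for (rep in 1:20) {
    x <- rand_arr(c(3, 3, 3), seed = rep)
    y <- rand_arr(c(3, 3, 3), seed = rep + 100)
    gc <- gradient_correlation(x, y)
    expect_true(gc >= -1 - 1e-12 && gc <= 1 + 1e-12)
    gl <- gc_loss(x, y, y, x)
    expect_true(gl >= -1e-12 && gl <= 2 + 1e-12)
  }
  expect_warning(ncc(array(1, c(4, 4, 4)), a), "constant")
})

test_that("gc_loss endpoints: perfect agreement 0, full anticorrelation 2", {
  x <- rand_arr(c(4, 4, 4), seed = 8)
  y <- rand_arr(c(4, 4, 4), seed = 9)
  expect_equal(gc_loss(x, x, y, y), 0, tolerance = 1e-12)
  expect_equal(gc_loss(x, 1 - x, y, -y + 2), 2, tolerance = 1e-12)
})

test_that("cycle loss equals the element-wise oracle", {
  x <- rand_arr(c(3, 4, 3), seed = 10); xr <- rand_arr(c(3, 4, 3), seed = 11)
  y <- rand_arr(c(4, 3, 3), seed = 12); yr <- rand_arr(c(4, 3, 3), seed = 13)
  oracle <- 0
  for (i in seq_along(x)) oracle <- oracle + abs(xr[i] - x[i]) / length(x)
  for (i in seq_along(y)) oracle <- oracle + abs(yr[i] - y[i]) / length(y)
  expect_equal(cycle_loss(x, xr, y, yr), oracle, tolerance = 1e-12)
  expect_equal(cycle_loss(x, x, y, y), 0)
  expect_equal(cycle_loss(x, x + 0.5, y, y), 0.5, tolerance = 1e-12)
})

test_that("aleatoric cycle loss reduces to the plain loss at log-sigma zero", {
  set.seed(14)
  for (rep in 1:100) {
    d <- sample(2:4, 3, replace = TRUE)
    x <- array(stats::rnorm(prod(d)), d); xr <- array(stats::rnorm(prod(d)), d)
    y <- array(stats::rnorm(prod(d)), d); yr <- array(stats::rnorm(prod(d)), d)
    z <- array(0, d)
    expect_equal(aleatoric_cycle_loss(x, xr, z, y, yr, z),
                 cycle_loss(x, xr, y, yr), tolerance = 1e-8)
  }
})

test_that("per-voxel aleatoric integrand is minimized at log(2r)", {
  # 1-D grid-search oracle over f(s) = r exp(-s) + s/2
  grid <- seq(-7, 7, by = 1e-4)
  for (r in c(0.1, 0.5, 1.3)) {
    f <- r * exp(-grid) + grid / 2
    s_star <- grid[which.min(f)]
    expect_equal(s_star, log(2 * r), tolerance = 1e-3)
    expect_equal(min(f), 0.5 + 0.5 * log(2 * r), tolerance = 1e-4)
    # the loss itself agrees with the oracle at the minimizer:
    # constant residual r, constant log-sigma s
    d <- c(3, 3, 3)
    x <- array(0, d); xr <- array(r, d)
    vals <- vapply(grid[seq(1, length(grid), by = 200)], function(s)
      aleatoric_cycle_loss(x, xr, array(s, d), x, x, array(0, d)) -
        aleatoric_cycle_loss(x, x, array(0, d), x, x, array(0, d)),
      numeric(1))
    expect_equal(min(vals), 0.5 + 0.5 * log(2 * r), tolerance = 2e-2)
  }
  # r = 0.5 gives the optimum exactly at log-sigma 0
  f <- 0.5 * exp(-grid) + grid / 2
  expect_equal(grid[which.min(f)], 0, tolerance = 1e-3)
})

test_that("uncertainty attenuates large residuals", {
  # raising log-sigma on voxels with |r| > exp(s)/2 lowers the integrand
  r <- 0.8; s <- 0
  expect_gt(abs(r), exp(s) / 2)
  f <- function(s) r * exp(-s) + s / 2
  expect_lt(f(s + 0.1), f(s))
  expect_error(
    aleatoric_cycle_loss(array(0, c(2, 2, 2)), array(0, c(2, 2, 2)),
                         array(NaN, c(2, 2, 2)), array(0, c(2, 2, 2)),
                         array(0, c(2, 2, 2)), array(0, c(2, 2, 2))),
    "non-finite")
})

test_that("adversarial losses follow the printed log-likelihood objective", {
  half <- array(0.5, c(2, 2, 2))
  al <- adversarial_losses(half, half)
  expect_equal(al$d_loss, log(4), tolerance = 1e-12)
  # perfect-discriminator limit
  expect_lt(adversarial_losses(array(1 - 1e-9, c(2, 2, 2)),
                               array(1e-9, c(2, 2, 2)))$d_loss, 1e-6)
  # generator loss decreases monotonically as D(fake) -> 1
  gl <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(p)
    adversarial_losses(half, array(p, c(2, 2, 2)))$g_loss, numeric(1))
  expect_true(all(diff(gl) < 0))
  expect_error(adversarial_losses(array(1.2, c(2, 2, 2)), half), "inside")
})

test_that("total objective assembles the weighted sum and is linear in weights", {
  w <- loss_weights()           # lambda 10, gamma 0.5
  rep1 <- total_objective(1, 1, 1, 1, weights = w)
  expect_equal(rep1$total, 12.5)
  expect_equal(total_objective(1, 1, 1, NULL, weights = w, use_gc = FALSE)$total, 12)
  expect_equal(total_objective(1, 1, 1, 1, weights = loss_weights(0, 0))$total, 2)
  # linearity in lambda and gamma
  t_of <- function(lam, gam)
    total_objective(0.3, -0.2, 0.7, 1.1, weights = loss_weights(lam, gam))$total
  expect_equal(t_of(4, 1) - t_of(2, 1), t_of(2, 1) - t_of(0, 1), tolerance = 1e-12)
  expect_equal(t_of(1, 4) - t_of(1, 2), t_of(1, 2) - t_of(1, 0), tolerance = 1e-12)
  # the report's total always equals the recomputed weighted sum
  expect_equal(rep1$total,
               rep1$l_adv_ct + rep1$l_adv_mr + 10 * rep1$l_cycle + 0.5 * rep1$l_gc)
})
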