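# Minimal volumetric neural-network layer: 3D convolutions (slice-gather +
# BLAS matrix products), instance normalization, activations, dropout,
# nearest-neighbour resampling, and Adam. Tensors are 4D arrays with
# dimensions (X, Y, Z, channels); one sample at a time (batching is a loop in
# the trainer, gradients are averaged). Every backward function returns the
# analytic derivative of a scalar loss w.r.t. its inputs and parameters;
# correctness is pinned by finite-difference checks in the test suite.

as_tensor4 <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

# ---- 3D convolution ---------------------------------------------------------

nn_conv_init <- function(c_in, c_out, k, gain = NULL, seed_stream = TRUE) {
  fan_in <- k^3 * c_in
  sd <- gain %||% sqrt(2 / fan_in)
  list(W = matrix(stats::rnorm(fan_in * c_out, 0, sd), fan_in, c_out),
       b = numeric(c_out))
}

# Linear gather indices for the im2col matrix: one column per
# (kernel offset, input channel). Cached per conv geometry — index building
# dominated the runtime when recomputed per call.
conv_idx_cache <- new.env(parent = emptyenv())

conv_gather_idx <- function(dp, od, k, stride, c_in) {
  key <- paste(c(dp, od, k, stride, c_in), collapse = "_")
  hit <- conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  ox <- seq(0L, by = stride, length.out = od[1])
  oy <- seq(0L, by = stride, length.out = od[2])
  oz <- seq(0L, by = stride, length.out = od[3])
  # linear index (1-based) of output-origin voxels in the padded grid
  base <- 1L + outer(outer(ox, oy * dp[1], `+`), oz * dp[1] * dp[2], `+`)
  base <- as.vector(base)
  K <- k^3 * c_in
  idx <- matrix(0L, length(base), K)
  j <- 1L
  voxels <- prod(dp)
  for (c in seq_len(c_in)) for (kz in seq_len(k)) for (ky in seq_len(k)) for (kx in seq_len(k)) {
    off <- (kx - 1L) + (ky - 1L) * dp[1] + (kz - 1L) * dp[1] * dp[2] +
      (c - 1L) * voxels
    idx[, j] <- base + off
    j <- j + 1L
  }
  out <- list(iv = as.vector(idx), n = length(base), K = K)
  conv_idx_cache[[key]] <- out
  out
}

conv_cols <- function(xp, od, k, stride, c_in) {
  idx <- conv_gather_idx(dim(xp)[1:3], od, k, stride, c_in)
  cols <- xp[idx$iv]
  dim(cols) <- c(idx$n, idx$K)
  cols
}

nn_conv_fwd <- function(x, par, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  x <- as_tensor4(x)
  d <- dim(x); c_in <- d[4]
  dp <- d[1:3] + 2L * pad
  if (any((dp - k) %% stride != 0))
    stopf("conv: input %s incompatible with kernel %d stride %d",
          paste(d[1:3], collapse = "x"), k, stride)
  od <- (dp - k) %/% stride + 1L
  if (any(od < 1L)) stopf("conv: input smaller than the receptive field")
  if (pad > 0L) {
    xp <- array(0, c(dp, c_in))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  } else xp <- x
  cols <- conv_cols(xp, od, k, stride, c_in)
  y <- cols %*% par$W
  y <- y + rep(par$b, each = nrow(y))
  list(y = array(y, c(od, ncol(par$W))),
       cache = list(cols = cols, xdim = d, od = od, k = k,
                    stride = stride, pad = pad))
}

# Permutation that turns the weight matrix (k^3*c_in x c_out) into the
# spatially flipped, channel-transposed matrix (k^3*c_out x c_in) used by the
# transposed convolution of the backward pass. Cached per geometry.
conv_flip_cache <- new.env(parent = emptyenv())

conv_flip_perm <- function(k, c_in, c_out) {
  key <- paste(k, c_in, c_out, sep = "_")
  hit <- conv_flip_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- expand.grid(kx = seq_len(k), ky = seq_len(k), kz = seq_len(k),
                   ci = seq_len(c_in), co = seq_len(c_out))
  src <- g$kx + (g$ky - 1L) * k + (g$kz - 1L) * k^2 + (g$ci - 1L) * k^3 +
    (g$co - 1L) * k^3 * c_in
  fx <- k + 1L - g$kx; fy <- k + 1L - g$ky; fz <- k + 1L - g$kz
  dst <- fx + (fy - 1L) * k + (fz - 1L) * k^2 + (g$co - 1L) * k^3 +
    (g$ci - 1L) * k^3 * c_out
  perm <- integer(length(src))
  perm[dst] <- src
  conv_flip_cache[[key]] <- perm
  perm
}

# Backward pass: dW/db from the cached gather matrix; dx as a transposed
# convolution (zero-stuffed dy convolved with the flipped kernel).
nn_conv_bwd <- function(dy, cache, par) {
  od <- cache$od; k <- cache$k; stride <- cache$stride; pad <- cache$pad
  d <- cache$xdim; c_in <- d[4]; c_out <- length(par$b)
  dym <- matrix(dy, prod(od), c_out)
  dW <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  pad2 <- k - 1L - pad
  dd <- (od - 1L) * stride + 1L
  up <- array(0, c(dd + 2L * pad2, c_out))
  up[pad2 + seq(1L, by = stride, length.out = od[1]),
     pad2 + seq(1L, by = stride, length.out = od[2]),
     pad2 + seq(1L, by = stride, length.out = od[3]), ] <- dy
  w_hat <- matrix(as.vector(par$W)[conv_flip_perm(k, c_in, c_out)],
                  k^3 * c_out, c_in)
  cols2 <- conv_cols(up, d[1:3], k, 1L, c_out)
  list(dx = array(cols2 %*% w_hat, d), dW = dW, db = db)
}

# ---- instance normalization -------------------------------------------------

nn_in_init <- function(channels) list(g = rep(1, channels), b = numeric(channels))

IN_EPS <- 1e-5

nn_in_fwd <- function(x, par) {
  d <- dim(x); n <- prod(d[1:3]); C <- d[4]
  xm <- matrix(x, n, C)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  v <- colSums(xc^2) / n
  inv <- 1 / sqrt(v + IN_EPS)
  xhat <- xc * rep(inv, each = n)
  y <- xhat * rep(par$g, each = n) + rep(par$b, each = n)
  list(y = array(y, d), cache = list(xhat = xhat, inv = inv, d = d))
}

nn_in_bwd <- function(dy, cache, par) {
  d <- cache$d; n <- prod(d[1:3]); C <- d[4]
  dym <- matrix(dy, n, C)
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dym * xhat)
  db <- colSums(dym)
  dxhat <- dym * rep(par$g, each = n)
  # dx = inv/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- rep(inv / n, each = n) *
    (n * dxhat - rep(s1, each = n) - xhat * rep(s2, each = n))
  list(dx = array(dx, d), dg = dg, db = db)
}

# ---- activations ------------------------------------------------------------

nn_lrelu_fwd <- function(x, alpha = 0.2) {
  m <- x < 0
  y <- x
  y[m] <- alpha * x[m]
  list(y = y, cache = m)
}
nn_lrelu_bwd <- function(dy, cache, alpha = 0.2) {
  dx <- dy
  dx[cache] <- alpha * dy[cache]
  dx
}

nn_tanh_fwd <- function(x) { y <- tanh(x); list(y = y, cache = y) }
nn_tanh_bwd <- function(dy, cache) dy * (1 - cache^2)

nn_sigmoid_fwd <- function(x) { y <- 1 / (1 + exp(-x)); list(y = y, cache = y) }
nn_sigmoid_bwd <- function(dy, cache) dy * cache * (1 - cache)

# ---- dropout ----------------------------------------------------------------

# Inverted dropout; draws from the current RNG stream when active.
nn_dropout_fwd <- function(x, rate, on) {
  if (!on || rate <= 0) return(list(y = x, cache = NULL))
  mask <- array(stats::rbinom(length(x), 1L, 1 - rate) / (1 - rate), dim(x))
  list(y = x * mask, cache = mask)
}
nn_dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

# ---- nearest-neighbour up/down sampling ------------------------------------

nn_up_fwd <- function(x) {
  d <- dim(x)
  ix <- rep(seq_len(d[1]), each = 2L)
  iy <- rep(seq_len(d[2]), each = 2L)
  iz <- rep(seq_len(d[3]), each = 2L)
  list(y = x[ix, iy, iz, , drop = FALSE], cache = d)
}
nn_up_bwd <- function(dy, cache) {
  d <- cache
  pool <- function(a, axis, n) {
    # sum adjacent pairs along `axis`
    if (axis == 1) a[seq(1, 2 * n, 2), , , , drop = FALSE] + a[seq(2, 2 * n, 2), , , , drop = FALSE]
    else if (axis == 2) a[, seq(1, 2 * n, 2), , , drop = FALSE] + a[, seq(2, 2 * n, 2), , , drop = FALSE]
    else a[, , seq(1, 2 * n, 2), , drop = FALSE] + a[, , seq(2, 2 * n, 2), , drop = FALSE]
  }
  dx <- pool(dy, 1, d[1])
  dx <- pool(dx, 2, d[2])
  pool(dx, 3, d[3])
}

nn_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[1:3], db[1:3]))
  y <- array(0, c(da[1:3], da[4] + db[4]))
  y[, , , seq_len(da[4])] <- a
  y[, , , da[4] + seq_len(db[4])] <- b
  y
}
nn_split <- function(dy, c_a) {
  d <- dim(dy)
  list(da = dy[, , , seq_len(c_a), drop = FALSE],
       db = dy[, , , c_a + seq_len(d[4] - c_a), drop = FALSE])
}

# ---- Adam -------------------------------------------------------------------

# params/grads are arbitrarily nested lists of numeric arrays with identical
# structure; state persists first/second moments and the step counter.
adam_init <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      if (!is.null(names(p))) g <- g[names(p)]
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

# elementwise sum of two nested grad lists
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    if (!is.null(names(a))) b <- b[names(a)]
    Map(grads_add, a, b)
  } else a + b
}

grads_scale <- function(a, s) {
  if (is.list(a)) lapply(a, grads_scale, s = s) else a * s
}
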