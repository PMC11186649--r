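# Generator and discriminator architectures. The generator is a 3D U-Net
# (encoder-decoder with skip connections) whose final 1x1x1 head splits into
# a tanh-squashed translation channel and, when uncertainty is modelled, an
# unbounded log-standard-deviation channel — so a single forward pass yields
# both the synthesized volume and its aleatoric map. Dropout units sit before
# every convolution and can be kept active at inference for Monte-Carlo
# sampling. The discriminator is a PatchGAN: strided convolutions ending in a
# grid of per-patch realness scores in (0, 1).

#' Generator architecture specification
#'
#' @param out_channels 1 (translation only) or 2 (translation + log-sigma
#'   uncertainty head).
#' @param depth number of resolution levels; input spatial dims must be
#'   divisible by `2^(depth - 1)`.
#' @param base_filters channels at the finest level; doubled per level.
#' @param dropout_rate dropout probability in `[0, 1)`, applied before every
#'   convolution and switchable at inference (Monte-Carlo dropout).
#' @return A `ucycle_generator_spec`.
#' @export
generator_spec <- function(out_channels = 2, depth = 4, base_filters = 16,
                           dropout_rate = 0.2) {
  if (!out_channels %in% c(1, 2)) stopf("out_channels must be 1 or 2")
  if (depth < 1) stopf("depth must be >= 1")
  if (base_filters < 1) stopf("base_filters must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must be in [0, 1)")
  structure(list(out_channels = as.integer(out_channels),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 dropout_rate = dropout_rate),
            class = "ucycle_generator_spec")
}

#' Discriminator architecture specification
#'
#' @param n_layers number of stride-2 convolution layers (`>= 1`); the patch
#'   score grid shrinks by `2^n_layers` relative to the input.
#' @param base_filters channels of the first layer; doubled per layer.
#' @return A `ucycle_discriminator_spec`.
#' @export
discriminator_spec <- function(n_layers = 3, base_filters = 16) {
  if (n_layers < 1) stopf("n_layers must be >= 1")
  if (base_filters < 1) stopf("base_filters must be >= 1")
  structure(list(n_layers = as.integer(n_layers),
                 base_filters = as.integer(base_filters)),
            class = "ucycle_discriminator_spec")
}

gen_filters <- function(spec) spec$base_filters * 2L^(seq_len(spec$depth) - 1L)

#' Build a generator network
#'
#' Weights are drawn from N(0, 0.02) (the customary initialization for
#' style-translation GANs) using the current RNG stream; seed the stream for
#' reproducible builds. Use [apply_generator()] to run it.
#'
#' @param spec a [generator_spec()].
#' @return A `ucycle_generator` holding the architecture and parameters.
#' @export
build_generator <- function(spec) {
  stopifnot(inherits(spec, "ucycle_generator_spec"))
  f <- gen_filters(spec)
  L <- spec$depth
  par <- list()
  c_prev <- 1L
  for (i in seq_len(L)) {
    par[[paste0("enc", i, "_conv")]] <- nn_conv_init(c_prev, f[i], 3L, gain = 0.02)
    par[[paste0("enc", i, "_in")]] <- nn_in_init(f[i])
    if (i < L) {
      par[[paste0("down", i, "_conv")]] <- nn_conv_init(f[i], f[i], 4L, gain = 0.02)
      par[[paste0("down", i, "_in")]] <- nn_in_init(f[i])
      c_prev <- f[i]
    }
  }
  for (i in rev(seq_len(L - 1))) {
    par[[paste0("dec", i, "_conv")]] <- nn_conv_init(f[i + 1] + f[i], f[i], 3L, gain = 0.02)
    par[[paste0("dec", i, "_in")]] <- nn_in_init(f[i])
  }
  par[["head_conv"]] <- nn_conv_init(f[1], spec$out_channels, 1L, gain = 0.02)
  structure(list(spec = spec, params = par), class = "ucycle_generator")
}

check_gen_input <- function(spec, d) {
  div <- 2L^(spec$depth - 1L)
  if (any(d %% div != 0))
    stopf("generator with depth %d needs spatial dims divisible by %d, got %s",
          spec$depth, div, paste(d, collapse = "x"))
}

# Full forward pass. `dropout_on` switches the stochastic units; `want_cache`
# retains every intermediate needed for backprop.
generator_forward <- function(gen, x, dropout_on = FALSE, want_cache = FALSE) {
  spec <- gen$spec; par <- gen$params
  rate <- spec$dropout_rate
  L <- spec$depth
  f <- gen_filters(spec)
  x <- as_vol_array(x)
  check_gen_input(spec, dim(x))
  h <- as_tensor4(x)
  cache <- if (want_cache) list() else NULL
  block_fwd <- function(h, name, k, stride) {
    dr <- nn_dropout_fwd(h, rate, dropout_on)
    cv <- nn_conv_fwd(dr$y, par[[paste0(name, "_conv")]], k, stride)
    nm <- nn_in_fwd(cv$y, par[[paste0(name, "_in")]])
    ac <- nn_lrelu_fwd(nm$y)
    list(y = ac$y, cache = list(dr = dr$cache, cv = cv$cache,
                                nm = nm$cache, ac = ac$cache))
  }
  skips <- vector("list", L)
  for (i in seq_len(L)) {
    b <- block_fwd(h, paste0("enc", i), 3L, 1L)
    skips[[i]] <- b$y
    if (want_cache) cache[[paste0("enc", i)]] <- b$cache
    if (i < L) {
      dbk <- block_fwd(b$y, paste0("down", i), 4L, 2L)
      h <- dbk$y
      if (want_cache) cache[[paste0("down", i)]] <- dbk$cache
    }
  }
  u <- skips[[L]]
  for (i in rev(seq_len(L - 1))) {
    up <- nn_up_fwd(u)
    cat_y <- nn_concat(up$y, skips[[i]])
    b <- block_fwd(cat_y, paste0("dec", i), 3L, 1L)
    u <- b$y
    if (want_cache) cache[[paste0("dec", i)]] <- c(b$cache, list(up = up$cache))
  }
  hd_dr <- nn_dropout_fwd(u, rate, dropout_on)
  hd <- nn_conv_fwd(hd_dr$y, par$head_conv, 1L, 1L, 0L)
  raw <- hd$y
  tn <- nn_tanh_fwd(raw[, , , 1, drop = FALSE])
  translation <- array(tn$y, dim(x))
  log_sigma <- if (spec$out_channels == 2L) array(raw[, , , 2], dim(x)) else NULL
  if (want_cache)
    cache$head <- list(dr = hd_dr$cache, cv = hd$cache, tanh = tn$cache)
  list(translation = translation, log_sigma = log_sigma, cache = cache)
}

# Backward pass: gradients of a scalar loss w.r.t. all parameters and the
# input, given d loss / d translation (and optionally d loss / d log_sigma).
generator_backward <- function(gen, cache, d_translation, d_log_sigma = NULL) {
  spec <- gen$spec; par <- gen$params
  L <- spec$depth
  f <- gen_filters(spec)
  grads <- list()
  block_bwd <- function(dy, name, bc) {
    dy <- nn_lrelu_bwd(dy, bc$ac)
    nm <- nn_in_bwd(dy, bc$nm, par[[paste0(name, "_in")]])
    cv <- nn_conv_bwd(nm$dx, bc$cv, par[[paste0(name, "_conv")]])
    grads[[paste0(name, "_in")]] <<- grads_add(grads[[paste0(name, "_in")]],
                                               list(g = nm$dg, b = nm$db))
    grads[[paste0(name, "_conv")]] <<- grads_add(grads[[paste0(name, "_conv")]],
                                                 list(W = cv$dW, b = cv$db))
    nn_dropout_bwd(cv$dx, bc$dr)
  }
  d3 <- dim(d_translation)
  dt <- nn_tanh_bwd(as_tensor4(d_translation), cache$head$tanh)
  if (spec$out_channels == 2L) {
    ds <- if (is.null(d_log_sigma)) array(0, d3) else d_log_sigma
    draw <- array(0, c(d3, 2L))
    draw[, , , 1] <- dt
    draw[, , , 2] <- ds
  } else {
    if (!is.null(d_log_sigma))
      stopf("generator has no log-sigma head")
    draw <- dt
  }
  hd <- nn_conv_bwd(draw, cache$head$cv, par$head_conv)
  grads$head_conv <- list(W = hd$dW, b = hd$db)
  du <- nn_dropout_bwd(hd$dx, cache$head$dr)
  d_skip_cat <- vector("list", L)
  for (i in seq_len(L - 1)) {
    dcat <- block_bwd(du, paste0("dec", i), cache[[paste0("dec", i)]])
    sp <- nn_split(dcat, f[i + 1])
    d_skip_cat[[i]] <- sp$db
    du <- nn_up_bwd(sp$da, cache[[paste0("dec", i)]]$up)
  }
  d_chain <- du  # gradient arriving at skips[[L]]
  dx <- NULL
  for (i in rev(seq_len(L))) {
    d_out <- d_chain
    if (i < L) d_out <- grads_add(d_out, d_skip_cat[[i]])
    d_in <- block_bwd(d_out, paste0("enc", i), cache[[paste0("enc", i)]])
    if (i > 1) {
      d_chain <- block_bwd(d_in, paste0("down", i - 1),
                           cache[[paste0("down", i - 1)]])
    } else dx <- d_in
  }
  list(grads = grads, dx = array(dx, d3))
}

#' Run a generator on a volume
#'
#' @param gen a [build_generator()] result.
#' @param x input [volume()] or 3D array with values in \[-1, 1\].
#' @param dropout logical; keep the stochastic dropout units active (draws
#'   from the current RNG stream)? `FALSE` gives the deterministic "hard"
#'   network.
#' @return list with `translation` (a [volume()] in \[-1, 1\]) and
#'   `log_sigma` (3D array, or `NULL` for a 1-channel generator).
#' @export
apply_generator <- function(gen, x, dropout = FALSE) {
  stopifnot(inherits(gen, "ucycle_generator"))
  spacing <- if (is_volume(x)) x$spacing else c(1, 1, 1)
  out <- generator_forward(gen, x, dropout_on = dropout, want_cache = FALSE)
  list(translation = volume(out$translation, spacing),
       log_sigma = out$log_sigma)
}

#' Build a PatchGAN discriminator
#'
#' @param spec a [discriminator_spec()].
#' @return A `ucycle_discriminator`.
#' @export
build_discriminator <- function(spec) {
  stopifnot(inherits(spec, "ucycle_discriminator_spec"))
  nf <- spec$base_filters * 2L^(seq_len(spec$n_layers) - 1L)
  par <- list()
  c_prev <- 1L
  for (i in seq_len(spec$n_layers)) {
    par[[paste0("d", i, "_conv")]] <- nn_conv_init(c_prev, nf[i], 4L, gain = 0.02)
    if (i > 1) par[[paste0("d", i, "_in")]] <- nn_in_init(nf[i])
    c_prev <- nf[i]
  }
  par[["final_conv"]] <- nn_conv_init(c_prev, 1L, 3L, gain = 0.02)
  structure(list(spec = spec, params = par), class = "ucycle_discriminator")
}

discriminator_forward <- function(disc, x, want_cache = FALSE) {
  spec <- disc$spec; par <- disc$params
  x <- as_vol_array(x)
  d <- dim(x)
  div <- 2L^spec$n_layers
  if (any(d %% div != 0) || any(d %/% div < 1L))
    stopf("discriminator with %d layers needs spatial dims divisible by %d (and >= %d), got %s",
          spec$n_layers, div, div, paste(d, collapse = "x"))
  h <- as_tensor4(x)
  cache <- if (want_cache) list() else NULL
  for (i in seq_len(spec$n_layers)) {
    cv <- nn_conv_fwd(h, par[[paste0("d", i, "_conv")]], 4L, 2L)
    h <- cv$y
    nm_cache <- NULL
    if (i > 1) {
      nm <- nn_in_fwd(h, par[[paste0("d", i, "_in")]])
      h <- nm$y; nm_cache <- nm$cache
    }
    ac <- nn_lrelu_fwd(h)
    h <- ac$y
    if (want_cache) cache[[i]] <- list(cv = cv$cache, nm = nm_cache, ac = ac$cache)
  }
  cv <- nn_conv_fwd(h, par$final_conv, 3L, 1L)
  sg <- nn_sigmoid_fwd(cv$y)
  if (want_cache) cache$final <- list(cv = cv$cache, sg = sg$cache)
  scores <- sg$y
  dim(scores) <- dim(scores)[1:3]
  list(scores = scores, cache = cache)
}

discriminator_backward <- function(disc, cache, d_scores) {
  spec <- disc$spec; par <- disc$params
  grads <- list()
  dy <- nn_sigmoid_bwd(as_tensor4(d_scores), cache$final$sg)
  cv <- nn_conv_bwd(dy, cache$final$cv, par$final_conv)
  grads$final_conv <- list(W = cv$dW, b = cv$db)
  dy <- cv$dx
  for (i in rev(seq_len(spec$n_layers))) {
    bc <- cache[[i]]
    dy <- nn_lrelu_bwd(dy, bc$ac)
    if (i > 1) {
      nm <- nn_in_bwd(dy, bc$nm, par[[paste0("d", i, "_in")]])
      grads[[paste0("d", i, "_in")]] <- list(g = nm$dg, b = nm$db)
      dy <- nm$dx
    }
    cv <- nn_conv_bwd(dy, bc$cv, par[[paste0("d", i, "_conv")]])
    grads[[paste0("d", i, "_conv")]] <- list(W = cv$dW, b = cv$db)
    dy <- cv$dx
  }
  d <- dim(dy)
  list(grads = grads, dx = array(dy, d[1:3]))
}

#' Score a volume with a PatchGAN discriminator
#'
#' @param disc a [build_discriminator()] result.
#' @param x input [volume()] or 3D array.
#' @return A 3D grid of per-patch realness scores in (0, 1).
#' @export
apply_discriminator <- function(disc, x) {
  stopifnot(inherits(disc, "ucycle_discriminator"))
  discriminator_forward(disc, x, want_cache = FALSE)$scores
}
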