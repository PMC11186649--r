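# Monte-Carlo dropout inference: epistemic uncertainty from the spread of T
# stochastic forward passes, aleatoric uncertainty from the mean of the
# predicted log-sigma maps.

# Run any generator-like object once. Accepts a ucycle_generator or a plain
# function(x, stochastic) returning list(translation, log_sigma); the latter
# lets tests substitute stubs with known output distributions.
gen_apply_raw <- function(generator, x, stochastic) {
  if (inherits(generator, "ucycle_generator")) {
    out <- generator_forward(generator, x, dropout_on = stochastic,
                             want_cache = FALSE)
    list(translation = out$translation, log_sigma = out$log_sigma)
  } else if (is.function(generator)) {
    generator(as_vol_array(x), stochastic)
  } else stopf("generator must be a ucycle_generator or a function")
}

#' Monte-Carlo dropout translation
#'
#' Performs `T` stochastic forward passes with dropout enabled. Each pass t
#' yields a synthesized volume and a log-sigma map; the voxel-wise mean of
#' the synthesized volumes is the predictive ("soft") mean, their voxel-wise
#' population variance (divide by `T`) is the epistemic uncertainty, and the
#' voxel-wise mean of the log-sigma maps is the aleatoric uncertainty.
#' Deterministic for a fixed `seed`.
#'
#' @param generator a [build_generator()] result with the 2-channel
#'   uncertainty head (or a function `(array, stochastic) -> list(translation,
#'   log_sigma)`).
#' @param input input [volume()] or 3D array.
#' @param T number of Monte-Carlo samples (default 20).
#' @param seed integer seed for the dropout draws.
#' @return A `ucycle_mc_result`: `predictive_mean` ([volume()]),
#'   `epistemic_variance` (3D array `>= 0`), `aleatoric_mean` (3D array of
#'   mean log-sigma), `n_samples`.
#' @export
mc_translate <- function(generator, input, T = 20, seed = 1) {
  if (T < 1) stopf("T must be >= 1")
  if (inherits(generator, "ucycle_generator") &&
      generator$spec$out_channels != 2L)
    stopf("Monte-Carlo aleatoric inference needs a generator with the log-sigma head (out_channels = 2)")
  spacing <- if (is_volume(input)) input$spacing else c(1, 1, 1)
  xd <- dim(as_vol_array(input))
  # accumulate deviations from the first sample: exactly zero variance when
  # every pass agrees (e.g. dropout rate 0), and well conditioned otherwise
  res <- with_seed(seed, {
    pivot <- NULL; s1 <- NULL; s2 <- NULL; sa <- array(0, xd)
    for (t in seq_len(T)) {
      out <- gen_apply_raw(generator, input, stochastic = TRUE)
      tr <- as_vol_array(out$translation)
      if (is.null(out$log_sigma))
        stopf("generator pass returned no log-sigma map")
      if (is.null(pivot)) {
        pivot <- tr; s1 <- array(0, xd); s2 <- array(0, xd)
      } else {
        d <- tr - pivot
        s1 <- s1 + d
        s2 <- s2 + d^2
      }
      sa <- sa + out$log_sigma
    }
    list(pivot = pivot, s1 = s1, s2 = s2, sa = sa)
  })
  m <- res$pivot + res$s1 / T
  v <- pmax(res$s2 / T - (res$s1 / T)^2, 0)
  structure(list(predictive_mean = volume(m, spacing),
                 epistemic_variance = array(v, xd),
                 aleatoric_mean = array(res$sa / T, xd),
                 n_samples = as.integer(T)),
            class = "ucycle_mc_result")
}

#' @export
print.ucycle_mc_result <- function(x, ...) {
  cat(sprintf("<ucycle_mc_result> T = %d, mean epistemic var %.3g, mean log-sigma %.3g\n",
              x$n_samples, mean(x$epistemic_variance), mean(x$aleatoric_mean)))
  invisible(x)
}

#' Deterministic ("hard") translation
#'
#' A single forward pass with dropout disabled: the prediction of the one
#' fixed set of weights, as opposed to the Monte-Carlo ("soft") mean.
#'
#' @inheritParams mc_translate
#' @return list with `translation` ([volume()]) and `log_sigma` (3D array or
#'   `NULL`).
#' @export
hard_translate <- function(generator, input) {
  spacing <- if (is_volume(input)) input$spacing else c(1, 1, 1)
  out <- gen_apply_raw(generator, input, stochastic = FALSE)
  list(translation = volume(as_vol_array(out$translation), spacing),
       log_sigma = out$log_sigma)
}

#' Write Monte-Carlo translation maps to NIfTI
#'
#' Emits the predictive mean, epistemic variance and aleatoric map side by
#' side as `<prefix>_mean.nii.gz`, `<prefix>_epistemic.nii.gz`,
#' `<prefix>_aleatoric.nii.gz`.
#'
#' @param result a [mc_translate()] result.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param exp_sigma write `exp(mean log-sigma)` (sigma units) instead of the
#'   raw mean log-sigma.
#' @return Named character vector of paths, invisibly.
#' @export
write_mc_result <- function(result, dir, prefix = "translated",
                            exp_sigma = FALSE) {
  stopifnot(inherits(result, "ucycle_mc_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- result$predictive_mean$spacing
  alea <- if (exp_sigma) exp(result$aleatoric_mean) else result$aleatoric_mean
  paths <- c(mean = file.path(dir, paste0(prefix, "_mean.nii.gz")),
             epistemic = file.path(dir, paste0(prefix, "_epistemic.nii.gz")),
             aleatoric = file.path(dir, paste0(prefix, "_aleatoric.nii.gz")))
  write_volume(result$predictive_mean, paths["mean"])
  write_volume(volume(result$epistemic_variance, sp), paths["epistemic"])
  write_volume(volume(alea, sp), paths["aleatoric"])
  invisible(paths)
}
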