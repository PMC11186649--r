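# Loss terms of the uncertainty-aware cycle-consistent translation model:
# adversarial terms, plain and aleatoric cycle-consistency, and the
# gradient-correlation prior. Each public function is a pure function of
# arrays/volumes; the *_grad_* helpers supply the analytic derivatives the
# training loop backpropagates (checked against finite differences in the
# test suite).

LOG_SIGMA_CLAMP <- 7
NCC_EPS <- 1e-8

#' Spatial gradients of a volume
#'
#' Forward finite differences along X, Y and Z; the final difference slice is
#' replicated so each component has the shape of the input. These are the
#' gradient fields entering the gradient-correlation prior.
#'
#' @param v a [volume()] or 3D array with at least 2 voxels per axis.
#' @return list with 3D arrays `gx`, `gy`, `gz`.
#' @export
spatial_gradients <- function(v) {
  x <- as_vol_array(v)
  d <- dim(x)
  if (any(d < 2L)) stopf("spatial gradients need >= 2 voxels per axis, got %s",
                         paste(d, collapse = "x"))
  fd <- function(a, axis) {
    n <- d[axis]
    idx_hi <- c(2:n, n); idx_lo <- c(1:(n - 1), n - 1)
    if (axis == 1) a[idx_hi, , , drop = FALSE] - a[idx_lo, , , drop = FALSE]
    else if (axis == 2) a[, idx_hi, , drop = FALSE] - a[, idx_lo, , drop = FALSE]
    else a[, , idx_hi, drop = FALSE] - a[, , idx_lo, drop = FALSE]
  }
  list(gx = fd(x, 1), gy = fd(x, 2), gz = fd(x, 3))
}

# Adjoint of the forward-difference-with-replication operator along one axis:
# maps a gradient-shaped array back to input space (used in backprop).
spatial_gradient_adjoint <- function(dg, axis) {
  d <- dim(dg); n <- d[axis]
  slice <- function(a, i) {
    if (axis == 1) a[i, , , drop = FALSE]
    else if (axis == 2) a[, i, , drop = FALSE]
    else a[, , i, drop = FALSE]
  }
  dv <- array(0, d)
  add <- function(dv, i, val) {
    if (axis == 1) dv[i, , ] <- dv[i, , , drop = FALSE] + val
    else if (axis == 2) dv[, i, ] <- dv[, i, , drop = FALSE] + val
    else dv[, , i] <- dv[, , i, drop = FALSE] + val
    dv
  }
  for (i in seq_len(n - 1)) {
    w <- slice(dg, i)
    if (i == n - 1) w <- w + slice(dg, n)  # replicated final slice
    dv <- add(dv, i + 1L, w)
    dv <- add(dv, i, -w)
  }
  dv
}

#' Normalized cross correlation of two grids
#'
#' `sum((a - mu_a) (b - mu_b)) / (sqrt(sum((a - mu_a)^2)) sqrt(sum((b - mu_b)^2)))`,
#' a value in \[-1, 1\] up to float tolerance. If either argument is constant
#' the correlation is undefined; the function returns 0 and emits a
#' degeneracy warning (denominators are guarded by a small epsilon).
#'
#' @param ga,gb numeric arrays of identical shape.
#' @return A single correlation value.
#' @export
ncc <- function(ga, gb) {
  if (!identical(dim(ga), dim(gb))) stopf("ncc: shape mismatch")
  ac <- ga - mean(ga); bc <- gb - mean(gb)
  sa <- sqrt(sum(ac^2)); sb <- sqrt(sum(bc^2))
  if (sa < NCC_EPS || sb < NCC_EPS) {
    warning("ncc: constant input, correlation undefined; returning 0",
            call. = FALSE)
    return(0)
  }
  sum(ac * bc) / (sa * sb)
}

# d ncc(ga, gb) / d gb, zero for degenerate inputs. No warning here: the
# forward pass already reported degeneracy.
ncc_grad_b <- function(ga, gb) {
  ac <- ga - mean(ga); bc <- gb - mean(gb)
  sa <- sqrt(sum(ac^2)); sb <- sqrt(sum(bc^2))
  if (sa < NCC_EPS || sb < NCC_EPS) return(array(0, dim(ga)))
  r <- sum(ac * bc) / (sa * sb)
  g <- ac / (sa * sb) - r * bc / sb^2
  # mean-subtraction of gb is part of the op: its adjoint removes the mean
  g - mean(g)
}

#' Gradient correlation between two volumes
#'
#' Arithmetic mean of the per-axis normalized cross correlations between the
#' spatial gradient fields of `a` and `b`. Equals 1 for identical edge
#' structure and -1 for fully inverted contrast; degenerate (constant
#' gradient) axes contribute 0.
#'
#' @param a,b [volume()]s or 3D arrays of identical shape.
#' @return Correlation in \[-1, 1\].
#' @export
gradient_correlation <- function(a, b) {
  ga <- spatial_gradients(a); gb <- spatial_gradients(b)
  (ncc(ga$gx, gb$gx) + ncc(ga$gy, gb$gy) + ncc(ga$gz, gb$gz)) / 3
}

# d [gradient_correlation(a, b)] / d b
gradient_correlation_grad_b <- function(a, b) {
  av <- as_vol_array(a); bv <- as_vol_array(b)
  ga <- spatial_gradients(av); gb <- spatial_gradients(bv)
  db <- spatial_gradient_adjoint(ncc_grad_b(ga$gx, gb$gx), 1) +
    spatial_gradient_adjoint(ncc_grad_b(ga$gy, gb$gy), 2) +
    spatial_gradient_adjoint(ncc_grad_b(ga$gz, gb$gz), 3)
  db / 3
}

#' Gradient-consistency loss
#'
#' `0.5 * ((1 - GradCorr(x, syn_ct)) + (1 - GradCorr(y, syn_mr)))`: penalizes
#' synthesized volumes whose edge structure departs from their source volume.
#' Acts as a structural prior; ranges over \[0, 2\].
#'
#' @param x,syn_ct source volume of domain A and its translation into B.
#' @param y,syn_mr source volume of domain B and its translation into A.
#' @return Loss value in \[0, 2\].
#' @export
gc_loss <- function(x, syn_ct, y, syn_mr) {
  0.5 * ((1 - gradient_correlation(x, syn_ct)) +
           (1 - gradient_correlation(y, syn_mr)))
}

#' Cycle-consistency loss
#'
#' Mean absolute error between each original volume and its reconstruction
#' after a round trip through both generators, summed over the two domains.
#'
#' @param x,x_rec domain-A volume and its A->B->A reconstruction.
#' @param y,y_rec domain-B volume and its B->A->B reconstruction.
#' @return Loss value `>= 0`.
#' @export
cycle_loss <- function(x, x_rec, y, y_rec) {
  xa <- as_vol_array(x); xr <- as_vol_array(x_rec)
  ya <- as_vol_array(y); yr <- as_vol_array(y_rec)
  if (!identical(dim(xa), dim(xr)) || !identical(dim(ya), dim(yr)))
    stopf("cycle_loss: shape mismatch")
  mean(abs(xr - xa)) + mean(abs(yr - ya))
}

clamp_log_sigma <- function(s) pmin(pmax(s, -LOG_SIGMA_CLAMP), LOG_SIGMA_CLAMP)

#' Aleatoric (heteroscedastic) cycle-consistency loss
#'
#' Per voxel, the reconstruction residual is attenuated by the predicted
#' standard deviation and the prediction is regularized by half its log:
#' `|residual| * exp(-log_sigma) + 0.5 * log_sigma`, averaged over voxels and
#' summed over the two domains. With `log_sigma == 0` everywhere this reduces
#' exactly to [cycle_loss()]. For a fixed residual `r` the per-voxel optimum
#' is `log_sigma = log(2 r)`, so the trained log-sigma map estimates the
#' irreducible reconstruction error — the aleatoric uncertainty. Log-sigma
#' values are clamped to \[-7, 7\] for numerical stability.
#'
#' @param x,x_rec,y,y_rec as in [cycle_loss()].
#' @param log_sigma_x,log_sigma_y voxel-wise predicted log standard deviation
#'   maps for the two reconstructions (3D arrays matching their domain).
#' @return Loss value.
#' @export
aleatoric_cycle_loss <- function(x, x_rec, log_sigma_x, y, y_rec, log_sigma_y) {
  term <- function(orig, rec, ls) {
    oa <- as_vol_array(orig); ra <- as_vol_array(rec); sa <- as_vol_array(ls)
    if (!identical(dim(oa), dim(ra)) || !identical(dim(oa), dim(sa)))
      stopf("aleatoric_cycle_loss: shape mismatch")
    s <- clamp_log_sigma(sa)
    if (any(!is.finite(s)))
      stopf("non-finite log-sigma map: training has diverged")
    mean(abs(ra - oa) * exp(-s) + 0.5 * s)
  }
  term(x, x_rec, log_sigma_x) + term(y, y_rec, log_sigma_y)
}

# Gradients of one domain term of the aleatoric cycle loss.
# Returns d/d rec and d/d log_sigma (zero where the clamp is active).
aleatoric_term_grads <- function(orig, rec, ls) {
  oa <- as_vol_array(orig); ra <- as_vol_array(rec); sa <- as_vol_array(ls)
  n <- length(oa)
  s <- clamp_log_sigma(sa)
  r <- ra - oa
  e <- exp(-s)
  d_rec <- sign(r) * e / n
  d_ls <- (-abs(r) * e + 0.5) / n
  d_ls[sa < -LOG_SIGMA_CLAMP | sa > LOG_SIGMA_CLAMP] <- 0
  list(d_rec = array(d_rec, dim(oa)), d_log_sigma = array(d_ls, dim(oa)))
}

# Gradient of one domain term of the plain cycle loss w.r.t. the
# reconstruction.
cycle_term_grad <- function(orig, rec) {
  oa <- as_vol_array(orig); ra <- as_vol_array(rec)
  array(sign(ra - oa) / length(oa), dim(oa))
}

#' Adversarial losses from discriminator patch scores
#'
#' The discriminator objective is the log likelihood
#' `E[log D(real)] + E[log(1 - D(fake))]`, which it maximizes; it is returned
#' negated as `d_loss`. The generator term is the non-saturating form
#' `-E[log D(fake)]`. Expectations average over the patch-score grid.
#'
#' @param d_real_scores,d_fake_scores patch-score grids with values in (0, 1).
#' @return list with `d_loss` and `g_loss`.
#' @export
adversarial_losses <- function(d_real_scores, d_fake_scores) {
  sr <- as.numeric(d_real_scores); sf <- as.numeric(d_fake_scores)
  if (any(sr <= 0 | sr >= 1) || any(sf <= 0 | sf >= 1))
    stopf("discriminator scores must lie strictly inside (0, 1)")
  list(d_loss = -(mean(log(sr)) + mean(log(1 - sf))),
       g_loss = -mean(log(sf)))
}

#' Loss weights of the full objective
#'
#' @param lambda_cycle weight of the (aleatoric) cycle-consistency term
#'   (default 10).
#' @param gamma_gc weight of the gradient-consistency term (default 0.5).
#' @return A `ucycle_loss_weights` list.
#' @export
loss_weights <- function(lambda_cycle = 10.0, gamma_gc = 0.5) {
  if (lambda_cycle < 0 || gamma_gc < 0) stopf("loss weights must be >= 0")
  structure(list(lambda_cycle = lambda_cycle, gamma_gc = gamma_gc),
            class = "ucycle_loss_weights")
}

#' Assemble the full training objective
#'
#' `total = l_adv_ct + l_adv_mr + lambda * cycle-term + gamma * gc-term`.
#' When the gradient-consistency ablation is off (`use_gc = FALSE`, or
#' `l_gc = NULL`) the gamma term is omitted. The cycle term is the aleatoric
#' version when uncertainty is modelled and the plain version otherwise; the
#' caller passes whichever value applies.
#'
#' @param l_adv_ct,l_adv_mr adversarial objectives of the two directions.
#' @param l_cycle (aleatoric) cycle-consistency value.
#' @param l_gc gradient-consistency value, or `NULL` when disabled.
#' @param weights a [loss_weights()].
#' @param use_gc logical; include the gamma term?
#' @return A `ucycle_loss_report` list with the components and `total`.
#' @export
total_objective <- function(l_adv_ct, l_adv_mr, l_cycle, l_gc = NULL,
                            weights = loss_weights(), use_gc = !is.null(l_gc)) {
  parts <- c(l_adv_ct, l_adv_mr, l_cycle, if (use_gc) l_gc)
  if (any(!is.finite(parts))) stopf("non-finite loss component")
  total <- l_adv_ct + l_adv_mr + weights$lambda_cycle * l_cycle +
    (if (use_gc) weights$gamma_gc * l_gc else 0)
  structure(list(l_adv_ct = l_adv_ct, l_adv_mr = l_adv_mr,
                 l_cycle = l_cycle, l_gc = if (use_gc) l_gc else NA_real_,
                 total = total),
            class = "ucycle_loss_report")
}

#' @export
print.ucycle_loss_report <- function(x, ...) {
  cat(sprintf("<loss> adv_ct %.4f  adv_mr %.4f  cycle %.4f  gc %s  total %.4f\n",
              x$l_adv_ct, x$l_adv_mr, x$l_cycle,
              if (is.na(x$l_gc)) "-" else sprintf("%.4f", x$l_gc), x$total))
  invisible(x)
}
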