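#' 3D scalar volume
#'
#' A `ucycle_volume` is the unit of translation: a 3D numeric grid plus voxel
#' spacing in millimetres. All model inputs and outputs (real volumes,
#' synthesized volumes, uncertainty maps) use this container. Axis order is
#' (X, Y, Z) with 0-based voxel indexing in user-facing coordinates; the same
#' convention is used by the finite-difference gradients of the
#' gradient-correlation loss.
#'
#' @param data numeric 3D array of finite values.
#' @param spacing numeric length-3 voxel spacing in mm (default isotropic 1).
#' @return An object of class `ucycle_volume`.
#' @examples
#' v <- volume(array(rnorm(8^3), c(8, 8, 8)))
#' dim(v$data)
#' @export
volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("volume data must be a 3D array, got %s dimension(s)",
          if (is.array(data)) length(dim(data)) else "no")
  if (!all(is.finite(data)))
    stopf("volume contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 positive numbers")
  structure(list(data = data, spacing = spacing), class = "ucycle_volume")
}

#' @export
print.ucycle_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ucycle_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "ucycle_volume")

# Accept either a ucycle_volume or a bare 3D array; return the array.
as_vol_array <- function(x) {
  if (is_volume(x)) return(x$data)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stopf("expected a ucycle_volume or a 3D array")
}

#' Read a volume from a NIfTI-1 file
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @return A [volume()] with the image data and voxel spacing.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stopf("expected a 3D NIfTI volume, got %dD data in %s",
          length(dim(arr)), path)
  volume(array(as.numeric(arr), dim(arr)), spacing = RNifti::pixdim(img))
}

#' Write a volume to a NIfTI-1 file
#'
#' Values are stored as 64-bit floats so that a write/read round trip is
#' value-exact; voxel spacing is carried in the NIfTI pixdim field.
#'
#' @param vol a [volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("directory does not exist: %s", dir)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Percentile-based intensity normalization to [-1, 1]
#'
#' Intensities are clipped at the `lo_pct` and `hi_pct` percentiles and then
#' mapped linearly onto \[-1, 1\], the range the translation networks operate
#' in (their output channel is tanh-squashed). A constant volume maps to all
#' zeros. The default percentiles (0.5, 99.5) are robust to isolated hot
#' voxels and are the identity in spirit on well-behaved synthetic data.
#'
#' @param vol a [volume()].
#' @param lo_pct,hi_pct clipping percentiles, `0 <= lo_pct < hi_pct <= 100`.
#' @return A normalized [volume()] with values in \[-1, 1\].
#' @export
normalize <- function(vol, lo_pct = 0.5, hi_pct = 99.5) {
  stopifnot(is_volume(vol))
  if (!(lo_pct >= 0 && lo_pct < hi_pct && hi_pct <= 100))
    stopf("require 0 <= lo_pct < hi_pct <= 100 (got %g, %g)", lo_pct, hi_pct)
  x <- vol$data
  qs <- stats::quantile(x, c(lo_pct, hi_pct) / 100, names = FALSE)
  lo <- qs[1]; hi <- qs[2]
  if (hi <= lo) {
    x[] <- 0
  } else {
    x <- pmin(pmax(x, lo), hi)
    x <- 2 * (x - lo) / (hi - lo) - 1
  }
  volume(x, vol$spacing)
}

#' Sample a random axis-aligned patch
#'
#' Draws a uniformly random sub-volume of the requested shape; used to build
#' training batches. Deterministic for a fixed `seed`; the caller's RNG state
#' is left untouched when a seed is supplied.
#'
#' @param vol a [volume()].
#' @param patch_shape integer length-3 patch size, componentwise `<=` the
#'   volume shape.
#' @param seed optional integer seed; if `NULL` the current RNG stream is used.
#' @return A [volume()] holding the patch (same spacing).
#' @export
sample_patch <- function(vol, patch_shape, seed = NULL) {
  stopifnot(is_volume(vol))
  d <- dim(vol$data)
  p <- as.integer(patch_shape)
  if (length(p) != 3L || any(p < 1L)) stopf("patch_shape must be 3 positive integers")
  if (any(p > d))
    stopf("patch shape (%s) exceeds volume shape (%s)",
          paste(p, collapse = "x"), paste(d, collapse = "x"))
  draw <- function() {
    start <- vapply(1:3, function(a) sample.int(d[a] - p[a] + 1L, 1L), integer(1))
    vol$data[start[1]:(start[1] + p[1] - 1L),
             start[2]:(start[2] + p[2] - 1L),
             start[3]:(start[3] + p[3] - 1L), drop = FALSE]
  }
  sub <- if (is.null(seed)) draw() else with_seed(seed, draw())
  volume(array(sub, p), vol$spacing)
}
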