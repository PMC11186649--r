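#' Specification of a synthetic two-modality spine phantom
#'
#' The phantom emulates the contrast relationship the translation model is
#' designed around: a curved column of vertebral bodies inside a soft-tissue
#' torso. Modality A (MR-like) renders bone dark and soft tissue bright with
#' per-subject random texture; modality B (CT-like) renders bone bright and
#' soft tissue near-uniform, i.e. the texture information present in A does
#' not exist in B. Ground-truth bone and tissue masks are returned so that
#' uncertainty maps can be summarized per region.
#'
#' @param grid_shape integer length-3 grid size in voxels (each `>= 8`).
#' @param n_vertebrae number of vertebral bodies stacked along Z (`>= 1`).
#' @param curve_amplitude lateral deviation of the column centerline in
#'   voxels — the "scoliosis" knob; 0 gives a straight axis-parallel column.
#' @param bone_intensity_a,bone_intensity_b bone intensity (pre-noise, on the
#'   \[-1, 1\] scale) in modalities A and B.
#' @param tissue_texture_sd standard deviation of the soft-tissue texture
#'   present only in modality A.
#' @param noise_sd standard deviation of additive Gaussian acquisition noise
#'   (`>= 0`), applied to both modalities.
#' @param seed integer seed; phantoms are bit-reproducible per seed.
#' @param spacing_scale multiplier on the inter-vertebra spacing (per-subject
#'   variation used by [make_unpaired_dataset()]).
#' @return A `ucycle_phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 32),
                         n_vertebrae = 5,
                         curve_amplitude = 3,
                         bone_intensity_a = -0.5,
                         bone_intensity_b = 0.9,
                         tissue_texture_sd = 0.15,
                         noise_sd = 0.02,
                         seed = 1,
                         spacing_scale = 1) {
  gs <- as.integer(grid_shape)
  if (length(gs) != 3L || any(gs < 8L))
    stopf("grid_shape must be 3 integers, each >= 8")
  if (n_vertebrae < 1) stopf("n_vertebrae must be >= 1")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (tissue_texture_sd < 0) stopf("tissue_texture_sd must be >= 0")
  if (spacing_scale <= 0) stopf("spacing_scale must be positive")
  spacing <- spacing_scale * gs[3] / (n_vertebrae + 1)
  if (spacing < 2.5)
    stopf("grid too small to contain %d vertebrae along a %d-voxel axis",
          n_vertebrae, gs[3])
  structure(list(grid_shape = gs, n_vertebrae = as.integer(n_vertebrae),
                 curve_amplitude = curve_amplitude,
                 bone_intensity_a = bone_intensity_a,
                 bone_intensity_b = bone_intensity_b,
                 tissue_texture_sd = tissue_texture_sd,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 spacing_scale = spacing_scale),
            class = "ucycle_phantom_spec")
}

# Geometry of the phantom: bone / tissue masks and vertebra centers.
# Deterministic given the spec (no RNG) so masks are invariant to noise_sd.
phantom_geometry <- function(spec) {
  gs <- spec$grid_shape
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]
  spacing <- spec$spacing_scale * nz / (spec$n_vertebrae + 1)
  zc <- spacing * seq_len(spec$n_vertebrae)
  zc <- zc + (nz / 2 - mean(zc))            # center the column axially
  cx <- nx / 2 + spec$curve_amplitude * sin(pi * zc / nz)
  cy <- rep(ny / 2, length(zc))
  rx <- 0.18 * min(nx, ny)
  rz <- 0.35 * spacing
  ix <- array(rep(seq_len(nx), times = ny * nz), gs)
  iy <- array(rep(rep(seq_len(ny), each = nx), times = nz), gs)
  iz <- array(rep(seq_len(nz), each = nx * ny), gs)
  bone <- array(FALSE, gs)
  for (v in seq_along(zc)) {
    q <- ((ix - cx[v]) / rx)^2 + ((iy - cy[v]) / rx)^2 + ((iz - zc[v]) / rz)^2
    bone <- bone | (q <= 1)
  }
  torso <- (((ix - nx / 2) / (0.42 * nx))^2 + ((iy - ny / 2) / (0.42 * ny))^2) <= 1
  tissue <- torso & !bone
  list(bone = bone, tissue = tissue,
       centers = cbind(x = cx, y = cy, z = zc))
}

#' Generate a two-modality spine phantom
#'
#' Renders the geometry of a [phantom_spec()] into the two pseudo-modalities.
#' The three random components (none in the geometry, texture in modality A,
#' acquisition noise) draw from independent seed-derived streams, so masks
#' are identical across different `noise_sd` values and the whole phantom is
#' bit-reproducible for a fixed seed. Intensities are clamped to \[-1, 1\].
#'
#' @param spec a [phantom_spec()].
#' @return A `ucycle_phantom`: list with `modality_a`, `modality_b`
#'   ([volume()]s), logical `bone_mask` and `tissue_mask`, and the `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "ucycle_phantom_spec"))
  gs <- spec$grid_shape
  geo <- phantom_geometry(spec)
  background_a <- -0.8; tissue_a <- 0.4
  background_b <- -0.8; tissue_b <- -0.2
  a <- array(background_a, gs)
  b <- array(background_b, gs)
  a[geo$tissue] <- tissue_a
  b[geo$tissue] <- tissue_b
  a[geo$bone] <- spec$bone_intensity_a
  b[geo$bone] <- spec$bone_intensity_b
  n_tis <- sum(geo$tissue)
  tex <- with_seed(child_seed(spec$seed, 10007L),
                   stats::rnorm(n_tis, 0, spec$tissue_texture_sd))
  a[geo$tissue] <- a[geo$tissue] + tex
  noise <- with_seed(child_seed(spec$seed, 20011L),
                     list(a = stats::rnorm(prod(gs), 0, spec$noise_sd),
                          b = stats::rnorm(prod(gs), 0, spec$noise_sd)))
  a <- pmin(pmax(a + noise$a, -1), 1)
  b <- pmin(pmax(b + noise$b, -1), 1)
  structure(list(modality_a = volume(array(a, gs)),
                 modality_b = volume(array(b, gs)),
                 bone_mask = geo$bone, tissue_mask = geo$tissue,
                 spec = spec),
            class = "ucycle_phantom")
}

#' @export
print.ucycle_phantom <- function(x, ...) {
  gs <- x$spec$grid_shape
  cat(sprintf("<ucycle_phantom> %dx%dx%d, %d vertebrae, bone %d vox, tissue %d vox\n",
              gs[1], gs[2], gs[3], x$spec$n_vertebrae,
              sum(x$bone_mask), sum(x$tissue_mask)))
  invisible(x)
}

#' Generate two unpaired sets of phantom volumes
#'
#' Draws `n_a` modality-A volumes and `n_b` modality-B volumes from
#' independently perturbed subjects: each subject jitters the curve amplitude
#' and the inter-vertebra spacing by up to +/-20% through its own derived
#' seed, and the A and B subject pools are disjoint, so there is no index
#' correspondence between the two lists — the unpaired regime the cycle
#' consistency constraint exists for.
#'
#' @param spec base [phantom_spec()]; per-subject specs are perturbations of it.
#' @param n_a,n_b number of volumes per domain (`>= 1`).
#' @param seed integer master seed for the subject perturbations.
#' @return list with elements `a` and `b`: lists of [volume()]s.
#' @export
make_unpaired_dataset <- function(spec, n_a, n_b, seed = spec$seed) {
  stopifnot(inherits(spec, "ucycle_phantom_spec"))
  if (n_a < 1 || n_b < 1) stopf("n_a and n_b must be >= 1")
  subject <- function(idx) {
    s <- child_seed(seed, idx)
    jit <- with_seed(s, stats::runif(2, 0.8, 1.2))
    sp <- phantom_spec(grid_shape = spec$grid_shape,
                       n_vertebrae = spec$n_vertebrae,
                       curve_amplitude = spec$curve_amplitude * jit[1],
                       bone_intensity_a = spec$bone_intensity_a,
                       bone_intensity_b = spec$bone_intensity_b,
                       tissue_texture_sd = spec$tissue_texture_sd,
                       noise_sd = spec$noise_sd,
                       seed = s,
                       spacing_scale = spec$spacing_scale * jit[2])
    make_phantom(sp)
  }
  list(a = lapply(seq_len(n_a), function(i) subject(i)$modality_a),
       b = lapply(seq_len(n_b), function(i) subject(n_a + i)$modality_b))
}

#' Write a phantom to NIfTI files
#'
#' Emits `<prefix>_modality_a.nii.gz`, `<prefix>_modality_b.nii.gz` and the
#' two masks as label volumes.
#'
#' @param phantom a [make_phantom()] result.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  stopifnot(inherits(phantom, "ucycle_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gs <- dim(phantom$bone_mask)
  paths <- c(
    modality_a = file.path(dir, paste0(prefix, "_modality_a.nii.gz")),
    modality_b = file.path(dir, paste0(prefix, "_modality_b.nii.gz")),
    bone_mask = file.path(dir, paste0(prefix, "_bone_mask.nii.gz")),
    tissue_mask = file.path(dir, paste0(prefix, "_tissue_mask.nii.gz")))
  write_volume(phantom$modality_a, paths["modality_a"])
  write_volume(phantom$modality_b, paths["modality_b"])
  write_volume(volume(array(as.numeric(phantom$bone_mask), gs)), paths["bone_mask"])
  write_volume(volume(array(as.numeric(phantom$tissue_mask), gs)), paths["tissue_mask"])
  invisible(paths)
}
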