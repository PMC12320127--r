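# ---------------------------------------------------------------------------
# Volume -> slice-bag preprocessing: 3D Gaussian smoothing (separable,
# reflect boundary), axial slicing, bilinear resize, intensity
# standardization.
# ---------------------------------------------------------------------------

fwhm_to_sigma <- function(fwhm_mm, voxel_mm = 2) {
  fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
}

# half-sample-symmetric reflection of 1-based index j into 1..n
reflect_index <- function(j, n) {
  while (any(j < 1L | j > n)) {
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
  }
  j
}

# Dense n x n smoothing matrix: sampled Gaussian, truncated at 4 sigma,
# normalized to sum 1, reflect boundary handling.
smooth_matrix_1d <- function(n, sigma) {
  radius <- max(1L, ceiling(4 * sigma))
  taps <- (-radius):radius
  k <- exp(-taps^2 / (2 * sigma^2))
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- reflect_index(i + taps, n)
    for (t in seq_along(taps)) M[i, js[t]] <- M[i, js[t]] + k[t]
  }
  M
}

apply_along_axis <- function(vol, M, axis) {
  d <- dim(vol)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
  v <- aperm(vol, perm)
  dv <- dim(v)
  dim(v) <- c(dv[1], prod(dv[-1]))
  v <- M %*% v
  dim(v) <- dv
  aperm(v, order(perm))
}

#' 3D Gaussian smoothing on the volume grid
#'
#' Separable Gaussian smoothing with
#' `sigma_vox = fwhm_mm / (2 sqrt(2 ln 2)) / voxel_mm` per axis, sampled
#' kernel truncated at 4 sigma and normalized to unit sum, reflect
#' (half-sample symmetric) boundary handling.
#'
#' @param volume A 3D numeric array or a `synthetic_volume`.
#' @param fwhm_mm Kernel full width at half maximum in millimetres
#'   (default 8).
#' @param voxel_mm Isotropic voxel size in millimetres (default 2).
#' @return Smoothed object of the same kind as the input.
#' @export
gaussian_smooth <- function(volume, fwhm_mm = 8, voxel_mm = 2) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive")
  is_sv <- inherits(volume, "synthetic_volume")
  vol <- if (is_sv) volume$intensities else unclass(volume)
  if (length(dim(vol)) != 3) stop("expected a 3D volume")
  sigma <- fwhm_to_sigma(fwhm_mm, voxel_mm)
  d <- dim(vol)
  for (ax in 1:3) vol <- apply_along_axis(vol, smooth_matrix_1d(d[ax], sigma), ax)
  if (is_sv) { volume$intensities <- vol; volume } else vol
}

resize_bilinear <- function(mat, target) {
  EBImage::resize(mat, w = target[1], h = target[2], antialias = FALSE)
}

#' Extract the model-ready bag of axial slices from a volume
#'
#' Takes all axial planes along the third (inferior-to-superior) axis, resizes
#' each bilinearly to `target_size`, and standardizes intensities. Modes:
#' `"volmean"` divides the whole volume by its global mean (proportional
#' scaling, removes scanner gain); `"zscore"` additionally z-scores each
#' slice after resizing (zero-variance slices map to all zeros); `"none"`
#' leaves intensities untouched.
#'
#' @param volume 3D array, `synthetic_volume`, or path to a NIfTI file.
#' @param row Manifest row (list/data.frame row) providing `subject_id`,
#'   `class`, `age`, `sex`, `split`; optional.
#' @param target_size Output slice size, default `c(224, 224)`.
#' @param standardize One of `"volmean"`, `"zscore"`, `"none"`.
#' @param norm_mask Optional logical mask restricting the proportional
#'   scaling to a reference region (e.g. [reference_region_mask()]); the
#'   default uses the whole volume.
#' @param expected_grid Expected volume dimensions (NULL to skip the check).
#' @return A `slice_bag`: list with `slices` (matrix, one column per slice,
#'   inferior to superior), `dim_slice`, `K`, `subject_id`, `covariates`,
#'   `label`, `split`.
#' @export
extract_bag <- function(volume, row = NULL, target_size = c(224, 224),
                        standardize = c("volmean", "zscore", "none"),
                        norm_mask = NULL, expected_grid = PET_GRID) {
  standardize <- match.arg(standardize)
  if (is.character(volume)) volume <- as.array(RNifti::readNifti(volume))
  if (inherits(volume, "synthetic_volume")) volume <- volume$intensities
  vol <- unclass(volume)
  if (length(dim(vol)) != 3) stop("expected a 3D volume")
  if (!is.null(expected_grid) && !all(dim(vol) == expected_grid))
    stop("unexpected grid shape: ", paste(dim(vol), collapse = "x"))
  if (!all(is.finite(vol))) stop("non-finite intensities in volume")
  if (standardize != "none") {
    mu <- if (is.null(norm_mask)) mean(vol) else mean(vol[norm_mask])
    if (mu > 0) vol <- vol / mu
  }
  K <- dim(vol)[3]
  npix <- prod(target_size)
  slices <- matrix(0, npix, K)
  for (k in seq_len(K)) {
    s <- resize_bilinear(vol[, , k], target_size)
    if (standardize == "zscore") {
      sd_ <- stats::sd(s)
      s <- if (is.na(sd_) || sd_ < 1e-12) s * 0 else (s - mean(s)) / sd_
    }
    slices[, k] <- as.vector(s)
  }
  structure(list(
    subject_id = if (!is.null(row)) as.character(row$subject_id) else NA_character_,
    slices = slices, dim_slice = as.integer(target_size), K = K,
    covariates = if (!is.null(row)) list(age = as.numeric(row$age),
                                         sex = as.character(row$sex)),
    label = if (!is.null(row)) as.character(row$class) else NA_character_,
    split = if (!is.null(row)) as.character(row$split) else NA_character_),
    class = "slice_bag")
}

#' Cohort reference image and deviation centering
#'
#' `reference_image` averages the preprocessed slices of a set of bags
#' (normally the training split) into a per-slice-index mean image — the
#' package's analogue of the normal-database template used in clinical
#' FDG-PET reading. `center_bags` subtracts it from every bag so the model
#' sees deviation images: the anatomy common to all subjects cancels and
#' only subject-specific regional signal remains.
#'
#' @param bags List of `slice_bag`s (use the training split for the
#'   reference).
#' @return `reference_image`: a `npix x K` matrix; `center_bags`: the bags
#'   with `ref` subtracted slice-wise.
#' @export
reference_image <- function(bags) {
  if (!length(bags)) stop("no bags")
  Reduce(`+`, lapply(bags, function(b) b$slices)) / length(bags)
}

#' @rdname reference_image
#' @param ref Reference image from [reference_image()].
#' @export
center_bags <- function(bags, ref) {
  lapply(bags, function(b) {
    if (!all(dim(b$slices) == dim(ref))) stop("reference/bag shape mismatch")
    b$slices <- b$slices - ref
    b
  })
}

#' Render, smooth and bag an entire phantom cohort
#'
#' Streams through the cohort: renders each subject's volume from its spec,
#' applies Gaussian smoothing, and extracts the slice bag, without keeping
#' volumes in memory.
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 8; `NA` to skip).
#' @param target_size Slice size after resizing.
#' @param standardize Standardization mode, see [extract_bag()].
#' @return Named list of `slice_bag` objects.
#' @export
cohort_bags <- function(cohort, fwhm_mm = 8, target_size = c(32, 32),
                        standardize = "volmean",
                        norm_mask = reference_region_mask(cohort$atlas)) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  man <- cohort$manifest
  bags <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    vol <- if (!is.null(cohort$volumes)) cohort$volumes[[i]]
           else render_volume(cohort$specs[[i]], cohort$atlas)
    if (!is.na(fwhm_mm)) vol <- gaussian_smooth(vol, fwhm_mm)
    bags[[i]] <- extract_bag(vol, man[i, ], target_size, standardize,
                             norm_mask = norm_mask)
  }
  stats::setNames(bags, man$subject_id)
}
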