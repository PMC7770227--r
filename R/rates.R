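# Per-subject annual change-rate maps and the analysis mask.

#' Per-subject annual change-rate map
#'
#' @param subject_id Subject identifier.
#' @param data 3-D array of per-voxel slope (change per year).
#' @param voxel_size_mm Voxel edge length in mm.
#' @return An object of class `rate_map`.
#' @export
rate_map <- function(subject_id, data, voxel_size_mm = 1) {
  stopifnot(length(dim(data)) == 3L)
  structure(list(subject_id = subject_id, data = data,
                 voxel_size_mm = voxel_size_mm),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("rate_map %s: grid %s, range [%.4g, %.4g] /yr\n", x$subject_id,
              paste(dim(x$data), collapse = "x"), min(x$data), max(x$data)))
  invisible(x)
}

#' Fit per-voxel annual change rates for one subject
#'
#' Ordinary least-squares slope of map value on acquisition time at every
#' voxel. With exactly two time points this reduces to the finite
#' difference.
#'
#' @param series A [subject_series()].
#' @return A [rate_map()] of slopes (change per year).
#' @export
fit_voxel_slopes <- function(series) {
  stopifnot(inherits(series, "subject_series"))
  tt <- series$times
  if (anyDuplicated(tt)) stopf("singular design: duplicated acquisition times")
  tc <- tt - mean(tt)
  w <- tc / sum(tc^2)            # OLS slope weights
  d <- series$grid_shape
  y <- vapply(series$maps, as.vector, numeric(prod(d)))
  slope <- array(as.vector(y %*% w), dim = d)
  rate_map(series$subject_id, slope, series$voxel_size_mm)
}

#' Smooth a rate or statistic map
#'
#' Isotropic Gaussian smoothing (see [smooth_volume()]); FWHM 0 is the
#' identity. Negative FWHM is an error.
#'
#' @param map A `rate_map`, or a plain 3-D array.
#' @param fwhm_mm Kernel FWHM in mm.
#' @param voxel_size_mm Voxel size; taken from the map when available.
#' @return Object of the same type as `map`.
#' @export
smooth_map <- function(map, fwhm_mm, voxel_size_mm = NULL) {
  if (any(fwhm_mm < 0)) stopf("fwhm_mm must be non-negative")
  if (inherits(map, "rate_map")) {
    vs <- voxel_size_mm %||% map$voxel_size_mm
    map$data <- smooth_volume(map$data, fwhm_mm, vs)
    map
  } else {
    smooth_volume(map, fwhm_mm, voxel_size_mm %||% 1)
  }
}

#' Fit and smooth rate maps for a whole cohort
#'
#' @param cohort An `sdn_cohort` (or list of `subject_series`).
#' @param fwhm_mm Smoothing FWHM in mm applied to the fitted rate maps
#'   (default 8, the conventional choice for this analysis).
#' @return List of [rate_map()]s, one per subject, in cohort order.
#' @export
cohort_rate_maps <- function(cohort, fwhm_mm = 8) {
  subjects <- if (inherits(cohort, "sdn_cohort")) cohort$subjects else cohort
  lapply(subjects, function(s) smooth_map(fit_voxel_slopes(s), fwhm_mm))
}

#' Analysis mask from tissue-probability maps
#'
#' Voxels whose across-subject mean tissue probability strictly exceeds the
#' threshold are retained (boundary values equal to the threshold are
#' excluded).
#'
#' @param tissue_maps List of 3-D arrays with values in `[0, 1]`.
#' @param threshold Inclusion threshold on the mean (default 0.2).
#' @return An object of class `analysis_mask`: logical 3-D array `data` and
#'   `n_voxels`.
#' @export
build_mask <- function(tissue_maps, threshold = 0.2) {
  if (length(tissue_maps) < 1L) stopf("need at least one tissue map")
  d <- dim(tissue_maps[[1]])
  acc <- array(0, dim = d)
  for (m in tissue_maps) {
    assert_same_grid(tissue_maps[[1]], m, "tissue maps")
    acc <- acc + m
  }
  keep <- (acc / length(tissue_maps)) > threshold
  if (!any(keep)) stopf("mask threshold excludes all voxels")
  analysis_mask(keep)
}

#' @rdname build_mask
#' @param data Logical 3-D array.
#' @export
analysis_mask <- function(data) {
  stopifnot(is.logical(data), length(dim(data)) == 3L)
  if (!any(data)) stopf("mask is empty")
  structure(list(data = data, n_voxels = sum(data)), class = "analysis_mask")
}

#' @export
print.analysis_mask <- function(x, ...) {
  cat(sprintf("analysis_mask: %d of %d voxels\n", x$n_voxels,
              length(x$data)))
  invisible(x)
}

#' Whole-grid mask for synthetic cohorts
#'
#' Synthetic cohorts carry signal at every voxel of the grid (there is no
#' tissue segmentation step), so the default mask keeps all voxels.
#'
#' @param grid_shape Length-3 integer vector.
#' @return An `analysis_mask` covering the grid.
#' @export
full_mask <- function(grid_shape) {
  analysis_mask(array(TRUE, dim = grid_shape))
}
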