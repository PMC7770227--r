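# Spatial similarity with a smoothness-matched permutation null, and
# goodness-of-fit network preference scoring.

#' Spatial correlation between two maps
#'
#' Pearson correlation of in-mask voxel values of two unthresholded maps.
#'
#' @param map_a,map_b 3-D arrays or `stat_map`s.
#' @param mask An `analysis_mask` (>= 3 voxels).
#' @return Correlation coefficient.
#' @export
spatial_correlation <- function(map_a, map_b, mask) {
  a <- map_values(map_a)[mask$data]
  b <- map_values(map_b)[mask$data]
  if (length(a) < 3L) stopf("mask must contain at least 3 voxels")
  if (anyNA(a) || anyNA(b)) stopf("maps must be finite inside the mask")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stopf("zero variance inside mask")
  stats::cor(a, b)
}

map_values <- function(x) {
  if (inherits(x, "stat_map") || inherits(x, "rate_map")) x$data else x
}

#' Permutation test of spatial similarity
#'
#' The observed correlation between an SDN map and a target map is compared
#' with a null in which the SDN side is replaced by Gaussian noise maps
#' smoothed to the SDN map's estimated smoothness (standardized within the
#' mask). The p-value uses the add-one rule on the two-sided exceedance
#' `(1 + #{|r_null| >= |r_obs|}) / (1 + n_perm)` and therefore never
#' returns 0.
#'
#' @param sdn_map SDN z map (array or `stat_map`).
#' @param target_map Target group degeneration z map.
#' @param mask An `analysis_mask`.
#' @param smoothness A `smoothness_estimate` from the SDN map's residuals,
#'   or FWHM in mm.
#' @param voxel_size_mm Voxel edge length in mm.
#' @param n_perm Number of noise maps (default 1000; < 100 draws a
#'   warning).
#' @param seed Integer seed.
#' @return An object of class `similarity_result`: `r_observed`,
#'   `null_sample`, `p_perm`, `n_perm`.
#' @export
permutation_similarity <- function(sdn_map, target_map, mask, smoothness,
                                   voxel_size_mm = 1, n_perm = 1000L,
                                   seed = 1L) {
  if (n_perm < 100L) warnf("n_perm = %d < 100; permutation p will be coarse", n_perm)
  fwhm <- if (inherits(smoothness, "smoothness_estimate")) {
    smoothness$fwhm_mm
  } else rep_len(smoothness, 3L)
  d <- dim(mask$data)
  if (any(fwhm_to_sigma(fwhm) / voxel_size_mm > d)) {
    stopf("smoothing kernel larger than the grid")
  }
  r_obs <- spatial_correlation(sdn_map, target_map, mask)
  tgt <- map_values(target_map)[mask$data]
  tgt <- (tgt - mean(tgt)) / stats::sd(tgt)
  nm <- length(tgt)
  null_sample <- with_seed(seed, {
    v <- standardized_noise_matrix(n_perm, fwhm, mask, voxel_size_mm)
    as.vector(crossprod(v, tgt)) / (nm - 1)       # Pearson r with target
  })
  p_perm <- (1 + sum(abs(null_sample) >= abs(r_obs))) / (1 + n_perm)
  structure(list(r_observed = r_obs, null_sample = null_sample,
                 p_perm = p_perm, n_perm = n_perm),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("spatial similarity: r = %.3f, permutation p = %.4g (%d perms)\n",
              x$r_observed, x$p_perm, x$n_perm))
  invisible(x)
}

#' Goodness-of-fit of a network to a target pattern
#'
#' `gof = mean(z inside the network) - mean(z in the mask but outside)`.
#' Higher scores mean the target pattern concentrates inside the network.
#'
#' @param network A [network_mask()] strictly inside the mask.
#' @param target_zmap Target z map (array or `stat_map`).
#' @param mask An `analysis_mask`.
#' @return An object of class `gof_result` with `mean_z_inside`,
#'   `mean_z_outside`, `gof`.
#' @export
gof <- function(network, target_zmap, mask) {
  net <- if (inherits(network, "network_mask")) network$data else network
  z <- map_values(target_zmap)
  inside <- net & mask$data
  outside <- mask$data & !net
  if (!any(inside)) stopf("network has no voxels inside the mask")
  if (!any(outside)) stopf("network covers the whole mask; outside set empty")
  mi <- mean(z[inside])
  mo <- mean(z[outside])
  structure(list(mean_z_inside = mi, mean_z_outside = mo, gof = mi - mo,
                 size_voxels = sum(inside),
                 percent = if (inherits(network, "network_mask")) network$percent else NA_real_),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("GOF = %.3f (inside %.3f - outside %.3f; %d voxels)\n",
              x$gof, x$mean_z_inside, x$mean_z_outside, x$size_voxels))
  invisible(x)
}

#' GOF profile over fixed-size top-percent networks
#'
#' Computes [gof()] at each [top_percent_mask()] of the SDN z map.
#'
#' @param sdn_zmap SDN z map used for the ranking.
#' @param target_zmap Target group z map.
#' @param mask An `analysis_mask`.
#' @param percents Vector of percentages (default 1:10).
#' @return Data frame: percent, size_voxels, mean_z_inside, mean_z_outside,
#'   gof.
#' @export
gof_profile <- function(sdn_zmap, target_zmap, mask, percents = 1:10) {
  rows <- lapply(percents, function(p) {
    g <- gof(top_percent_mask(sdn_zmap, mask, p), target_zmap, mask)
    data.frame(percent = p, size_voxels = g$size_voxels,
               mean_z_inside = g$mean_z_inside,
               mean_z_outside = g$mean_z_outside, gof = g$gof)
  })
  do.call(rbind, rows)
}
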