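# Epicenter identification and seed-based synchronized degeneration
# network (SDN) mapping.

#' Spherical seed region
#'
#' Member voxels are those whose center-to-center distance from the seed
#' center is at most `radius_mm` (closed ball on voxel centers), clipped to
#' the grid and, when given, the analysis mask.
#'
#' @param center Length-3 voxel coordinate of the seed center.
#' @param radius_mm Sphere radius in mm (default 6).
#' @param voxel_size_mm Voxel edge length in mm.
#' @param grid_shape Length-3 grid dimensions.
#' @param mask Optional `analysis_mask`.
#' @return An object of class `sphere_seed` with `member_voxels`
#'   (coordinate matrix) and `member_index` (linear indices).
#' @export
sphere_seed <- function(center, radius_mm = 6, voxel_size_mm = 1,
                        grid_shape, mask = NULL) {
  center <- as.integer(center)
  r_vox <- radius_mm / voxel_size_mm
  span <- floor(r_vox)
  off <- as.matrix(expand.grid(dx = -span:span, dy = -span:span, dz = -span:span))
  off <- off[rowSums(off^2) <= r_vox^2, , drop = FALSE]
  coords <- sweep(off, 2L, center, "+")
  ok <- coords[, 1] >= 1L & coords[, 1] <= grid_shape[1] &
        coords[, 2] >= 1L & coords[, 2] <= grid_shape[2] &
        coords[, 3] >= 1L & coords[, 3] <= grid_shape[3]
  coords <- coords[ok, , drop = FALSE]
  idx <- coords[, 1] + (coords[, 2] - 1L) * grid_shape[1] +
    (coords[, 3] - 1L) * grid_shape[1] * grid_shape[2]
  if (!is.null(mask)) {
    keep <- mask$data[idx]
    coords <- coords[keep, , drop = FALSE]
    idx <- idx[keep]
  }
  if (length(idx) == 0L) stopf("seed has no member voxels inside the mask")
  structure(list(center = center, radius_mm = radius_mm,
                 voxel_size_mm = voxel_size_mm, grid_shape = grid_shape,
                 member_voxels = coords, member_index = as.integer(idx)),
            class = "sphere_seed")
}

#' @export
print.sphere_seed <- function(x, ...) {
  cat(sprintf("sphere_seed at (%s), radius %g mm: %d voxels\n",
              paste(x$center, collapse = ", "), x$radius_mm,
              nrow(x$member_voxels)))
  invisible(x)
}

#' Identify epicenter seeds from surviving clusters
#'
#' One sphere seed per surviving cluster, centered at the cluster's
#' peak-|statistic| voxel (ties broken by smallest linear scan-order
#' index).
#'
#' @param map The contrast [stat_map()] the clusters came from.
#' @param thresholded Result of [apply_cluster_threshold()] on `map`.
#' @param radius_mm Seed sphere radius in mm (default 6).
#' @param mask Optional `analysis_mask` restricting seed membership.
#' @return List of [sphere_seed()]s, one per cluster.
#' @export
find_epicenters <- function(map, thresholded, radius_mm = 6, mask = NULL) {
  cl <- thresholded$clusters
  if (nrow(cl) == 0L) stopf("no epicenters at current threshold")
  lapply(seq_len(nrow(cl)), function(i) {
    sphere_seed(c(cl$peak_x[i], cl$peak_y[i], cl$peak_z[i]),
                radius_mm = radius_mm, voxel_size_mm = map$voxel_size_mm,
                grid_shape = dim(map$data), mask = mask)
  })
}

#' Mean rate within a seed region
#'
#' @param map A [rate_map()].
#' @param seed A [sphere_seed()].
#' @return Unweighted mean rate over the seed's member voxels.
#' @export
extract_seed_rate <- function(map, seed) {
  stopifnot(inherits(map, "rate_map"), inherits(seed, "sphere_seed"))
  mean(map$data[seed$member_index])
}

#' Map a synchronized degeneration network from a seed
#'
#' Voxel-wise GLM (in the control group) of voxel rate on the per-subject
#' seed mean rate plus centered nuisance covariates; the z-converted t map
#' of the seed regressor is the SDN coupling map.
#'
#' @param rate_maps List of [rate_map()]s (control group).
#' @param seed_values Per-subject seed mean rates (same order).
#' @param covariates Data frame of nuisance covariates (or NULL).
#' @param mask An `analysis_mask`.
#' @param seed The [sphere_seed()] (metadata; optional).
#' @return An object of class `sdn_map`: `zmap` (z `stat_map`), `tmap`,
#'   `seed`, and attribute-free residuals under `residuals` for smoothness
#'   estimation.
#' @export
map_sdn <- function(rate_maps, seed_values, covariates = NULL, mask,
                    seed = NULL) {
  n <- length(rate_maps)
  if (length(seed_values) != n) stopf("one seed value per rate map required")
  if (stats::sd(seed_values) == 0) stopf("zero-variance seed values")
  k <- if (is.null(covariates)) 0L else NCOL(covariates)
  if (n < k + 2L) stopf("need n >= number of covariates + 2")
  cv <- cbind(seed = seed_values - mean(seed_values),
              if (!is.null(covariates)) as.matrix(covariates))
  design <- make_design(groups = NULL, covariates = cv)
  tmap <- fit_ancova(rate_maps, design, c(seed = 1), mask,
                     keep_residuals = TRUE)
  res <- attr(tmap, "residuals")
  attr(tmap, "residuals") <- NULL
  zmap <- suppressWarnings(t_to_z(tmap))
  structure(list(zmap = zmap, tmap = tmap, seed = seed, residuals = res),
            class = "sdn_map")
}

#' @export
print.sdn_map <- function(x, ...) {
  cat("sdn_map: seed-coupling z map\n")
  if (!is.null(x$seed)) print(x$seed)
  invisible(x)
}

#' Binarize an SDN map at the cluster-FWE criterion
#'
#' Positive-coupling voxels (seed regressor > 0) exceeding the two-sided
#' voxel height threshold are clustered and clusters at least
#' `min_extent` large are retained ("synchronized degeneration" is positive
#' covariance; set `direction = "two_sided"` to admit both signs).
#'
#' @param sdn An `sdn_map`.
#' @param threshold A `cluster_threshold`.
#' @param direction `"positive"` (default) or `"two_sided"`.
#' @return A [network_mask()] with provenance `"cluster_fwe_threshold"`.
#' @export
sdn_network_mask <- function(sdn, threshold, direction = c("positive", "two_sided")) {
  direction <- match.arg(direction)
  zmap <- sdn$zmap
  thr <- apply_cluster_threshold(zmap, threshold)
  keep <- thr$mask
  if (direction == "positive") keep <- keep & !is.na(zmap$data) & zmap$data > 0
  if (!any(keep)) stopf("empty network at current threshold")
  network_mask(keep, provenance = "cluster_fwe_threshold")
}

#' Binarized network region set
#'
#' @param data Logical 3-D array.
#' @param provenance `"cluster_fwe_threshold"` or `"top_percent"`.
#' @param percent Retained percentage for fixed-size masks.
#' @return An object of class `network_mask`.
#' @export
network_mask <- function(data, provenance = c("cluster_fwe_threshold", "top_percent"),
                         percent = NA_real_) {
  provenance <- match.arg(provenance)
  if (!any(data)) stopf("network mask is empty")
  structure(list(data = data, size_voxels = sum(data),
                 provenance = provenance, percent = percent),
            class = "network_mask")
}

#' @export
print.network_mask <- function(x, ...) {
  cat(sprintf("network_mask (%s%s): %d voxels\n", x$provenance,
              if (!is.na(x$percent)) sprintf(", top %g%%", x$percent) else "",
              x$size_voxels))
  invisible(x)
}

#' Fixed-size network mask from the top percentage of voxels
#'
#' Ranks in-mask voxels by z descending and retains
#' `ceiling(percent/100 * n_mask)` voxels; ties at the cut are broken by
#' scan order.
#'
#' @param zmap A z [stat_map()] (any statistic map works).
#' @param mask An `analysis_mask`.
#' @param percent Percentage in (0, 100].
#' @return A [network_mask()] with provenance `"top_percent"`.
#' @export
top_percent_mask <- function(zmap, mask, percent) {
  if (percent <= 0 || percent > 100) stopf("percent must be in (0, 100]")
  inidx <- which(mask$data)
  z <- zmap$data[inidx]
  n_keep <- ceiling(percent / 100 * length(inidx))
  ord <- order(-z, inidx)       # descending z, scan order on ties
  keep_idx <- inidx[ord[seq_len(n_keep)]]
  out <- array(FALSE, dim = dim(mask$data))
  out[keep_idx] <- TRUE
  network_mask(out, provenance = "top_percent", percent = percent)
}

#' Dice overlap between two binary masks
#'
#' @param a,b Logical arrays (or `network_mask`s).
#' @return Dice coefficient `2|A&B| / (|A| + |B|)`.
#' @export
dice_overlap <- function(a, b) {
  if (inherits(a, "network_mask")) a <- a$data
  if (inherits(b, "network_mask")) b <- b$data
  2 * sum(a & b) / (sum(a) + sum(b))
}
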