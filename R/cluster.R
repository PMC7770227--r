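# Cluster-extent familywise-error control: residual smoothness estimation
# and Monte-Carlo simulation of the maximum cluster size under smooth
# Gaussian noise, in the tradition of the AFNI 3dFWHMx/3dClustSim pair
# (re-implemented here as a Gaussian-FWHM Monte Carlo).

#' Estimate spatial smoothness (FWHM) of residual maps
#'
#' Classical Gaussian-random-field estimator: per axis, the FWHM follows
#' from the variance of first differences relative to the map variance,
#' `FWHM = voxel_size * sqrt(-2*log(2) / log(1 - varDelta / (2*var)))`.
#' Estimates are averaged across maps; the combined value is the geometric
#' mean over axes. Each axis estimate is floored at half a voxel.
#'
#' @param maps List of 3-D residual maps (or a single map).
#' @param mask An `analysis_mask`; differences use in-mask neighbor pairs.
#' @param voxel_size_mm Voxel edge length in mm.
#' @return An object of class `smoothness_estimate`: `fwhm_mm` (length 3)
#'   and `combined_fwhm_mm`.
#' @export
estimate_fwhm <- function(maps, mask, voxel_size_mm = 1) {
  if (!is.list(maps)) maps <- list(maps)
  if (length(maps) < 1L) stopf("need at least one residual map")
  m <- mask$data
  d <- dim(m)
  if (any(d < 2L)) stopf("mask grid needs >= 2 voxels along each axis")
  per_map <- vapply(maps, function(x) {
    v <- stats::var(x[m])
    if (!is.finite(v) || v <= 0) stopf("flat residuals: zero variance in mask")
    vapply(1:3, function(ax) {
      idx_lo <- slice_indices(d, ax, head = TRUE)
      idx_hi <- slice_indices(d, ax, head = FALSE)
      pair <- m[idx_lo] & m[idx_hi]
      if (!any(pair)) return(NA_real_)
      dif <- x[idx_hi][pair] - x[idx_lo][pair]
      ratio <- mean(dif^2) / (2 * v)
      fwhm_from_diff_ratio(ratio, voxel_size_mm)
    }, 0)
  }, numeric(3))
  fwhm <- rowMeans(per_map, na.rm = TRUE)
  fwhm <- pmax(fwhm, 0.5 * voxel_size_mm)
  structure(list(fwhm_mm = fwhm,
                 combined_fwhm_mm = prod(fwhm)^(1 / 3),
                 voxel_size_mm = voxel_size_mm),
            class = "smoothness_estimate")
}

fwhm_from_diff_ratio <- function(ratio, voxel_size_mm) {
  if (!is.finite(ratio) || ratio >= 1) return(0.5 * voxel_size_mm)
  ratio <- max(ratio, 1e-12)
  voxel_size_mm * sqrt(-2 * log(2) / log(1 - ratio))
}

# Logical index arrays selecting the lower/upper members of neighbor pairs
# along one axis.
slice_indices <- function(d, axis, head = TRUE) {
  out <- array(TRUE, dim = d)
  n <- d[axis]
  keep <- if (head) seq_len(n - 1L) else seq(2L, n)
  if (axis == 1L) out[-keep, , ] <- FALSE
  if (axis == 2L) out[, -keep, ] <- FALSE
  if (axis == 3L) out[, , -keep] <- FALSE
  out
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("smoothness: FWHM = %s mm (combined %.2f mm)\n",
              paste(sprintf("%.2f", x$fwhm_mm), collapse = " x "),
              x$combined_fwhm_mm))
  invisible(x)
}

# Neighbor offset table for 6/18/26 connectivity.
connectivity_offsets <- function(connectivity = 18L) {
  if (!connectivity %in% c(6L, 18L, 26L)) stopf("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6"  = nz == 1,
                 "18" = nz >= 1 & rowSums(off != 0) <= 2,
                 "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

#' Label connected components of a logical 3-D array
#'
#' Union-find over the neighbor graph of foreground voxels under 6-, 18- or
#' 26-connectivity. Components are numbered by the scan-order position of
#' their first voxel.
#'
#' @param x Logical 3-D array.
#' @param connectivity 6, 18 or 26 (default 18).
#' @return Integer array of component labels (0 = background).
#' @export
label_clusters <- function(x, connectivity = 18L) {
  d <- dim(x)
  labels <- array(0L, dim = d)
  vox <- which(x)
  n <- length(vox)
  if (n == 0L) return(labels)
  comp_id <- array(0L, dim = d)
  comp_id[vox] <- seq_len(n)
  coords <- arrayInd(vox, d)
  off <- connectivity_offsets(connectivity)
  # undirected edges: half the offsets suffice
  key <- off[, 1] + 3 * off[, 2] + 9 * off[, 3]
  off <- off[key > 0, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(off))) {
    nx <- coords[, 1] + off[k, 1]
    ny <- coords[, 2] + off[k, 2]
    nz <- coords[, 3] + off[k, 3]
    ok <- nx >= 1L & nx <= d[1] & ny >= 1L & ny <= d[2] &
          nz >= 1L & nz <= d[3]
    if (!any(ok)) next
    lin <- nx[ok] + (ny[ok] - 1L) * d[1] + (nz[ok] - 1L) * d[1] * d[2]
    j <- comp_id[lin]
    i <- which(ok)[j > 0L]
    j <- j[j > 0L]
    for (e in seq_along(i)) {
      ri <- find(i[e]); rj <- find(j[e])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels[vox] <- match(roots, unique(roots))
  labels
}

#' Simulate the cluster-extent threshold for smooth Gaussian noise
#'
#' Monte-Carlo analogue of the AFNI cluster-simulation approach: Gaussian
#' noise fields are smoothed to the estimated FWHM, standardized within the
#' mask, thresholded two-sided at the voxel p-value, and the maximum
#' cluster size recorded. The minimum extent is the smallest `k` with
#' `P(max cluster >= k) <= cluster_alpha`.
#'
#' @param smoothness A `smoothness_estimate`, or FWHM in mm (scalar or
#'   length 3).
#' @param mask An `analysis_mask`.
#' @param voxel_size_mm Voxel edge length in mm.
#' @param voxel_p Two-sided voxel-level p threshold (default 0.005).
#' @param cluster_alpha Familywise alpha for the extent (default 0.05).
#' @param n_sim Number of noise simulations (>= 1000 recommended; fewer
#'   draws a warning).
#' @param seed Integer seed.
#' @param connectivity Cluster-forming connectivity (default 18).
#' @return An object of class `cluster_threshold` with `min_extent_voxels`,
#'   the simulation settings, and the simulated max-cluster sizes.
#' @export
simulate_cluster_threshold <- function(smoothness, mask, voxel_size_mm = 1,
                                       voxel_p = 0.005, cluster_alpha = 0.05,
                                       n_sim = 1000L, seed = 1L,
                                       connectivity = 18L) {
  if (voxel_p <= 0 || voxel_p >= 1) stopf("voxel_p must be in (0, 1)")
  if (cluster_alpha <= 0 || cluster_alpha > 1) stopf("cluster_alpha must be in (0, 1]")
  if (n_sim < 1000L) warnf("n_sim = %d < 1000; extent threshold will be noisy", n_sim)
  fwhm <- if (inherits(smoothness, "smoothness_estimate")) {
    smoothness$fwhm_mm
  } else rep_len(smoothness, 3L)
  d <- dim(mask$data)
  if (any(fwhm_to_sigma(fwhm) / voxel_size_mm > d)) {
    stopf("smoothing kernel larger than the grid")
  }
  inmask <- mask$data
  inidx <- which(inmask)
  zthr <- stats::qnorm(1 - voxel_p / 2)
  max_sizes <- with_seed(seed, {
    out <- integer(n_sim)
    done <- 0L
    while (done < n_sim) {
      k <- min(100L, n_sim - done)
      z <- standardized_noise_matrix(k, fwhm, mask, voxel_size_mm, chunk = k)
      for (j in seq_len(k)) {
        hit <- inidx[abs(z[, j]) > zthr]
        out[done + j] <- if (length(hit) == 0L) 0L else {
          supra <- array(FALSE, dim = d)
          supra[hit] <- TRUE
          labs <- label_clusters(supra, connectivity)
          max(tabulate(labs[labs > 0L]))
        }
      }
      done <- done + k
    }
    out
  })
  min_extent <- min_extent_from_max_sizes(max_sizes, cluster_alpha)
  structure(list(voxel_p = voxel_p, cluster_alpha = cluster_alpha,
                 min_extent_voxels = min_extent, n_simulations = n_sim,
                 fwhm_mm = fwhm, connectivity = connectivity,
                 max_cluster_sizes = max_sizes, seed = seed),
            class = "cluster_threshold")
}

min_extent_from_max_sizes <- function(max_sizes, alpha) {
  n <- length(max_sizes)
  for (k in seq_len(max(max_sizes) + 1L)) {
    if (sum(max_sizes >= k) / n <= alpha) return(k)
  }
  max(max_sizes) + 1L
}

#' @export
print.cluster_threshold <- function(x, ...) {
  cat(sprintf(
    "cluster_threshold: voxel p < %g (two-sided), FWE alpha = %g -> k >= %d voxels (%d sims, FWHM %s mm, %d-connectivity)\n",
    x$voxel_p, x$cluster_alpha, x$min_extent_voxels, x$n_simulations,
    paste(sprintf("%.2f", x$fwhm_mm), collapse = "x"), x$connectivity))
  invisible(x)
}

#' Apply a cluster-extent threshold to a statistic map
#'
#' Thresholds the map two-sided at the voxel p-value (using the t or normal
#' distribution as appropriate), labels suprathreshold clusters, and keeps
#' those at least as large as the simulated minimum extent.
#'
#' @param map A t or z [stat_map()].
#' @param threshold A `cluster_threshold`.
#' @return List with `mask` (logical array of surviving voxels), `labels`
#'   (integer array over surviving clusters), and `clusters` (data frame:
#'   cluster id, size, peak statistic, peak voxel coordinates).
#' @export
apply_cluster_threshold <- function(map, threshold) {
  stopifnot(inherits(map, "stat_map"), inherits(threshold, "cluster_threshold"))
  h <- stat_height_threshold(map, threshold$voxel_p)
  x <- map$data
  supra <- !is.na(x) & abs(x) > h
  if (!is.null(map$mask)) supra <- supra & map$mask$data
  labs <- label_clusters(supra, threshold$connectivity)
  sizes <- tabulate(labs[labs > 0L])
  keep_ids <- which(sizes >= threshold$min_extent_voxels)
  out_mask <- array(FALSE, dim = dim(x))
  out_labs <- array(0L, dim = dim(x))
  rows <- list()
  for (i in seq_along(keep_ids)) {
    id <- keep_ids[i]
    vox <- which(labs == id)
    out_mask[vox] <- TRUE
    out_labs[vox] <- i
    peak_vox <- vox[which.max(abs(x[vox]))]  # ties: first in scan order
    pc <- arrayInd(peak_vox, dim(x))
    rows[[i]] <- data.frame(cluster = i, size = sizes[id],
                            peak_stat = x[peak_vox],
                            peak_x = pc[1], peak_y = pc[2], peak_z = pc[3])
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), size = integer(0),
               peak_stat = numeric(0), peak_x = integer(0),
               peak_y = integer(0), peak_z = integer(0))
  list(mask = out_mask, labels = out_labs, clusters = clusters)
}

stat_height_threshold <- function(map, voxel_p) {
  switch(map$stat_kind,
         t = stats::qt(1 - voxel_p / 2, df = map$df),
         z = stats::qnorm(1 - voxel_p / 2),
         stopf("cluster thresholding needs a t or z map"))
}
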