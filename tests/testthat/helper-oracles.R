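# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's computational paths.

# OLS slope via explicit normal equations.
oracle_slope <- function(y, t) {
  n <- length(t)
  (n * sum(t * y) - sum(t) * sum(y)) / (n * sum(t^2) - sum(t)^2)
}

# Direct (non-separable) 3-D convolution with an explicit product kernel
# and zero padding.
oracle_conv3d <- function(x, kernel1d) {
  d <- dim(x)
  r <- (length(kernel1d) - 1L) / 2L
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) for (dk in -r:r) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          kk >= 1 && kk <= d[3]) {
        acc <- acc + x[ii, jj, kk] *
          kernel1d[di + r + 1] * kernel1d[dj + r + 1] * kernel1d[dk + r + 1]
      }
    }
    out[i, j, k] <- acc
  }
  out
}

# Pearson correlation from explicit sums.
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  num / den
}

# Contrast t statistic via lm() on a per-voxel basis.
oracle_lm_t <- function(y, X, cvec) {
  fit <- stats::lm(y ~ 0 + X)
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  as.numeric(cvec %*% beta) / sqrt(as.numeric(t(cvec) %*% V %*% cvec))
}

# Connected components by repeated whole-set scanning (O(n^2) flood fill),
# structured differently from the package's union-find.
oracle_label <- function(x, connectivity = 18L) {
  d <- dim(x)
  vox <- which(x)
  coords <- arrayInd(vox, d)
  n <- length(vox)
  labels <- integer(n)
  is_neighbor <- function(a, b) {
    dd <- abs(a - b)
    if (max(dd) > 1 || all(dd == 0)) return(FALSE)
    nz <- sum(dd > 0)
    switch(as.character(connectivity),
           "6" = nz == 1, "18" = nz <= 2, "26" = TRUE)
  }
  lab <- 0L
  for (s in seq_len(n)) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    queue <- s
    labels[s] <- lab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (t in seq_len(n)) {
        if (labels[t] == 0L && is_neighbor(coords[cur, ], coords[t, ])) {
          labels[t] <- lab
          queue <- c(queue, t)
        }
      }
    }
  }
  out <- array(0L, dim = d)
  out[vox] <- labels
  out
}

# Lattice points within a closed ball, by explicit enumeration.
oracle_sphere_count <- function(radius_vox) {
  span <- floor(radius_vox)
  cnt <- 0L
  for (dx in -span:span) for (dy in -span:span) for (dz in -span:span) {
    if (dx^2 + dy^2 + dz^2 <= radius_vox^2) cnt <- cnt + 1L
  }
  cnt
}

# Small helper cohorts --------------------------------------------------

tiny_series <- function(times, values_by_time, dim3 = c(12, 12, 12),
                        voxel_size_mm = 1) {
  maps <- lapply(values_by_time, function(v) array(v, dim = dim3))
  subject_series("tst", "HC",
                 data.frame(age = 70, sex = 0, education = 12, tiv = 1.4e6),
                 times = times, maps = maps, voxel_size_mm = voxel_size_mm)
}

random_rate_maps <- function(n, d = c(8, 8, 8), sd = 1) {
  lapply(seq_len(n), function(i) {
    rate_map(sprintf("S%02d", i), array(rnorm(prod(d), sd = sd), dim = d))
  })
}

# A small cohort spec with a strong single planted network, suitable for
# fast pipeline smoke tests.
tiny_pipeline_spec <- function(seed = 1L) {
  cohort_spec(
    grid_shape = c(20L, 20L, 20L),
    n_per_group = c(HC = 16L, MCIs = 7L, MCIp = 6L, AD = 7L),
    epicenters = list(c(10L, 10L, 10L)),
    network_radius_vox = 3,
    loading_core_vox = 2, loading_shoulder_vox = 1,
    group_mean_rates = c(HC = -0.004, MCIs = -0.008, MCIp = -0.045,
                         AD = -0.050),
    factor_sd = 0.012, rate_noise_sd = 0.004, noise_sd = 0.006,
    smoothing_fwhm_mm = 6, two_timepoint_fraction = 0,
    seed = seed
  )
}
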