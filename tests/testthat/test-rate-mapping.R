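test_that("exact linear series give exact slopes", {
  s <- tiny_series(c(0, 1, 2), list(1.0, 0.9, 0.8))
  rm1 <- fit_voxel_slopes(s)
  expect_equal(unique(as.vector(rm1$data)), -0.1, tolerance = 1e-12)
})

test_that("two time points reduce to the finite difference", {
  s <- tiny_series(c(0, 1.5), list(1.0, 0.95))
  rm1 <- fit_voxel_slopes(s)
  expect_equal(rm1$data[1, 1, 1], (0.95 - 1.0) / 1.5, tolerance = 1e-12)
})

test_that("random series match the normal-equations oracle per voxel", {
  set.seed(5)
  d <- c(4, 4, 4)
  times <- c(0, 0.9, 2.1)
  maps <- lapply(times, function(t) array(rnorm(prod(d)), dim = d))
  s <- subject_series("r", "HC", NULL, times, maps)
  rm1 <- fit_voxel_slopes(s)
  for (v in sample(prod(d), 10)) {
    y <- vapply(maps, function(m) m[[v]], 0)
    expect_equal(rm1$data[[v]], oracle_slope(y, times), tolerance = 1e-10)
  }
})

test_that("duplicated acquisition times are a singular design", {
  s <- tiny_series(c(0, 1, 2), list(1, 1, 1))
  s$times <- c(0, 1, 1)   # bypass the constructor check deliberately
  expect_error(fit_voxel_slopes(s), "singular design")
})

test_that("noise-free cohorts are recovered exactly", {
  spec <- cohort_spec(
    grid_shape = c(14L, 14L, 14L),
    n_per_group = c(HC = 3L, MCIs = 2L, MCIp = 2L, AD = 2L),
    epicenters = list(c(7L, 7L, 7L)), network_radius_vox = 3,
    loading_core_vox = 2, loading_shoulder_vox = 1,
    noise_sd = 0, rate_noise_sd = 0.005, two_timepoint_fraction = 0,
    seed = 4L
  )
  coh <- generate_cohort(spec)
  for (i in c(1, 5, 9)) {
    rm_i <- fit_voxel_slopes(coh$subjects[[i]])
    expect_equal(as.vector(rm_i$data), coh$truth$rates[i, ],
                 tolerance = 1e-10)
  }
})

test_that("the slope estimator is unbiased under visit noise", {
  spec <- cohort_spec(
    grid_shape = c(12L, 12L, 12L),
    n_per_group = c(HC = 200L, MCIs = 2L, MCIp = 2L, AD = 2L),
    epicenters = list(), noise_sd = 0.02, smoothing_fwhm_mm = 0,
    rate_noise_sd = 0.005, two_timepoint_fraction = 0, seed = 12L
  )
  coh <- generate_cohort(spec)
  hc <- which(coh$covariates$group == "HC")
  v <- 777L
  err <- vapply(hc, function(i) {
    fit_voxel_slopes(coh$subjects[[i]])$data[[v]] - coh$truth$rates[i, v]
  }, 0)
  # slope noise sd for 3 annual visits is noise_sd / sqrt(2)
  se <- (0.02 / sqrt(2)) / sqrt(length(hc))
  expect_lt(abs(mean(err)), 3 * se)
})

test_that("mask construction follows the strict mean > threshold rule", {
  d <- c(3, 3, 3)
  m1 <- array(0.3, dim = d); m2 <- array(0.3, dim = d)
  m1[1, 1, 1] <- 0.2; m2[1, 1, 1] <- 0.2   # mean exactly at threshold
  m1[2, 1, 1] <- 0;   m2[2, 1, 1] <- 0
  mask <- build_mask(list(m1, m2), threshold = 0.2)
  expect_false(mask$data[1, 1, 1])  # boundary excluded
  expect_false(mask$data[2, 1, 1])
  expect_true(mask$data[3, 3, 3])
  expect_equal(mask$n_voxels, prod(d) - 2)
})

test_that("random tissue maps match the mean-and-compare oracle", {
  set.seed(9)
  d <- c(5, 5, 5)
  maps <- lapply(1:4, function(i) array(runif(prod(d)), dim = d))
  mask <- build_mask(maps, 0.5)
  manual <- Reduce(`+`, maps) / 4 > 0.5
  expect_identical(mask$data, manual)
})

test_that("thresholds that exclude everything are an error", {
  expect_error(build_mask(list(array(0.1, c(3, 3, 3))), 0.2),
               "excludes all voxels")
})
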