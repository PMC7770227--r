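small_spec <- function(...) {
  args <- list(
    grid_shape = c(14L, 14L, 14L),
    n_per_group = c(HC = 4L, MCIs = 2L, MCIp = 2L, AD = 2L),
    epicenters = list(c(7L, 7L, 7L)),
    network_radius_vox = 3, loading_core_vox = 2, loading_shoulder_vox = 1,
    two_timepoint_fraction = 0
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_spec, args)
}

test_that("a fixed seed reproduces the cohort bitwise", {
  s <- small_spec(seed = 99L)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$cognition, b$cognition)
  expect_identical(a$truth, b$truth)
})

test_that("cohort generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_cohort(small_spec(seed = 5L)))
  expect_identical(.Random.seed, before)
})

test_that("noise-free construction declines exactly at the baseline rate", {
  s <- small_spec(
    epicenters = list(), noise_sd = 0, rate_noise_sd = 0,
    baseline_rate = -0.02,
    covariate_effects = c(age = 0, sex = 0, education = 0, tiv = 0),
    seed = 2L
  )
  coh <- generate_cohort(s)
  sub <- coh$subjects[[1]]
  for (k in seq_along(sub$times)) {
    expect_equal(sub$maps[[k]],
                 array(1 - 0.02 * sub$times[k], dim = s$grid_shape),
                 tolerance = 1e-12)
  }
})

test_that("fully degenerate specs warn but remain valid", {
  expect_warning(
    small_spec(epicenters = list(), noise_sd = 0, rate_noise_sd = 0,
               factor_sd = 0, baseline_rate = 0,
               covariate_effects = c(age = 0, sex = 0, education = 0, tiv = 0),
               group_mean_rates = c(HC = 0, MCIs = 0, MCIp = 0, AD = 0)),
    "degenerate"
  )
  # a nonzero baseline slope is signal, not degeneracy
  expect_no_warning(
    small_spec(epicenters = list(), noise_sd = 0, rate_noise_sd = 0,
               factor_sd = 0, baseline_rate = -0.02,
               group_mean_rates = c(HC = 0, MCIs = 0, MCIp = 0, AD = 0))
  )
})

test_that("group mean voxel rates converge to beta0 + lambda * group rate", {
  s <- small_spec(
    n_per_group = c(HC = 150L, MCIs = 2L, MCIp = 2L, AD = 2L),
    rate_noise_sd = 0.004,
    covariate_effects = c(age = 0, sex = 0, education = 0, tiv = 0),
    seed = 31L
  )
  coh <- generate_cohort(s)
  hc <- coh$covariates$group == "HC"
  lam <- coh$truth$loading_maps[[1]]
  vox_core <- which(lam == 1)[1]          # a unit-loading voxel
  vox_out <- which(lam == 0)[1]           # outside the network
  expected_core <- s$baseline_rate + 1 * s$group_mean_rates[[1]]["HC"]
  se_core <- sqrt(s$factor_sd^2 + s$rate_noise_sd^2) / sqrt(sum(hc))
  got_core <- mean(coh$truth$rates[hc, vox_core])
  expect_lt(abs(got_core - expected_core), 3 * se_core)
  got_out <- mean(coh$truth$rates[hc, vox_out])
  expect_lt(abs(got_out - s$baseline_rate), 3 * s$rate_noise_sd / sqrt(sum(hc)))
})

test_that("in-network rate covariance approaches lambda^2 * factor_sd^2", {
  d <- c(14L, 14L, 14L)
  lam <- array(0, dim = d)
  ctr <- c(7, 7, 7)
  for (i in 1:14) for (j in 1:14) for (k in 1:14) {
    if (sum((c(i, j, k) - ctr)^2) <= 9) lam[i, j, k] <- 0.5
  }
  s <- cohort_spec(
    grid_shape = d, n_per_group = c(HC = 500L, MCIs = 2L, MCIp = 2L, AD = 2L),
    epicenters = list(ctr), loading_maps = list(lam),
    rate_noise_sd = 0, noise_sd = 0.005, smoothing_fwhm_mm = 0,
    covariate_effects = c(age = 0, sex = 0, education = 0, tiv = 0),
    factor_sd = 0.01, two_timepoint_fraction = 0, seed = 61L
  )
  coh <- generate_cohort(s)
  hc <- coh$covariates$group == "HC"
  invox <- which(lam > 0)
  v1 <- invox[1]; v2 <- invox[length(invox)]
  got <- cov(coh$truth$rates[hc, v1], coh$truth$rates[hc, v2])
  expected <- 0.25 * s$factor_sd^2
  expect_lt(abs(got - expected), 0.2 * expected)
})

test_that("generated noise smoothness matches the requested FWHM within 20%", {
  s <- cohort_spec(
    grid_shape = c(32L, 32L, 32L), voxel_size_mm = 1,
    n_per_group = c(HC = 3L, MCIs = 2L, MCIp = 2L, AD = 2L),
    epicenters = list(), baseline_rate = 0,
    covariate_effects = c(age = 0, sex = 0, education = 0, tiv = 0),
    rate_noise_sd = 0, noise_sd = 1, smoothing_fwhm_mm = 2.5,
    two_timepoint_fraction = 0, seed = 8L
  )
  coh <- generate_cohort(s)
  # baseline maps are 1 + noise exactly (t = 0, zero rates)
  noise_maps <- lapply(coh$subjects, function(x) x$maps[[1]] - 1)
  est <- estimate_fwhm(noise_maps, full_mask(s$grid_shape), 1)
  expect_lt(abs(est$combined_fwhm_mm - 2.5) / 2.5, 0.2)
})

test_that("cognitive scores are coupled to the planted network rate", {
  s <- small_spec(
    n_per_group = c(HC = 30L, MCIs = 10L, MCIp = 10L, AD = 10L),
    cognitive_score_sd = 0.05, cognitive_slope_sd = 0.05,
    seed = 17L
  )
  coh <- generate_cohort(s)
  mm <- coh$truth$cognitive_slopes[, "MMSE"]
  expect_gt(cor(mm, coh$truth$netrate), 0.9)
  # CFT copy is uncoupled by default
  cf <- coh$truth$cognitive_slopes[, "CFT_copy"]
  expect_lt(abs(cor(cf, coh$truth$netrate)), 0.35)
})

test_that("series invariants are enforced", {
  expect_error(tiny_series(c(0, 0), list(1, 2)), "strictly increasing")
  expect_error(
    subject_series("a", "HC", NULL, times = 0:2,
                   maps = list(array(0, c(3, 3, 3)))),
    "at least 2"
  )
})
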