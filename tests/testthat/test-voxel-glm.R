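mask8 <- full_mask(c(8, 8, 8))

test_that("identical data in both groups gives a contrast t of exactly 0", {
  set.seed(1)
  base <- array(rnorm(8^3), dim = c(8, 8, 8))
  rms <- lapply(1:8, function(i) rate_map(paste0("s", i), base))
  design <- make_design(factor(rep(c("A", "B"), each = 4)))
  sm <- fit_ancova(rms, design, c(A = 1, B = -1), mask8)
  expect_true(all(sm$data == 0))
})

test_that("ANCOVA contrast t matches the lm() oracle on random instances", {
  set.seed(2)
  for (rep in 1:5) {
    n <- 8
    groups <- factor(rep(c("A", "B"), each = 4))
    covs <- data.frame(age = rnorm(n), tiv = rnorm(n))
    rms <- random_rate_maps(n)
    design <- make_design(groups, covs)
    cvec <- expand_contrast_vec <- c(1, -1, 0, 0)
    sm <- fit_ancova(rms, design, cvec, mask8)
    for (v in sample(8^3, 5)) {
      y <- vapply(rms, function(m) m$data[[v]], 0)
      expect_equal(sm$data[[v]], oracle_lm_t(y, design$X, cvec),
                   tolerance = 1e-10)
    }
    expect_equal(sm$df, n - ncol(design$X))
  }
})

test_that("one-sample t matches the closed form", {
  d <- c(8, 8, 8)
  rms <- lapply(c(1, 2, 3), function(v) rate_map(paste0("s", v), array(v, d)))
  sm <- fit_one_sample(rms, covariates = NULL, mask = mask8)
  expect_equal(sm$data[1, 1, 1], 2 / (1 / sqrt(3)), tolerance = 1e-10)

  rms0 <- lapply(1:3, function(i) rate_map(paste0("z", i), array(0, d)))
  sm0 <- fit_one_sample(rms0, covariates = NULL, mask = mask8)
  expect_true(all(sm0$data == 0))
  expect_error(fit_one_sample(rms0[1:2], NULL, mask8), "n >= 3")
})

test_that("zero-variance nonzero rates clamp to +/-38 in z with a warning", {
  d <- c(8, 8, 8)
  rms <- lapply(1:4, function(i) rate_map(paste0("c", i), array(0.5, d)))
  sm <- fit_one_sample(rms, covariates = NULL, mask = mask8)
  expect_true(all(is.infinite(sm$data)))
  expect_warning(zm <- t_to_z(sm), "clamped")
  expect_true(all(zm$data == 38))
})

test_that("t to z conversion is symmetric, limit-correct and matches quadrature", {
  sm <- function(t, df) stat_map(array(t, c(2, 2, 2)), "t", df = df)
  expect_equal(t_to_z(sm(0, 7))$data[1], 0)
  expect_equal(t_to_z(sm(1.5, 1e6))$data[1], 1.5, tolerance = 1e-3)
  z1 <- t_to_z(sm(2.5, 30))$data[1]
  z2 <- t_to_z(sm(-2.5, 30))$data[1]
  expect_equal(z1, -z2, tolerance = 1e-12)
  # quadrature oracle: upper tail area of the t density, then inverse normal
  p_tail <- integrate(function(x) dt(x, df = 30), 2.5, Inf,
                      rel.tol = 1e-12)$value
  expect_equal(z1, qnorm(1 - p_tail), tolerance = 1e-8)
  expect_error(t_to_z(sm(1, 0)), "df")
})

test_that("contrast maps are invariant to affine covariate rescaling", {
  set.seed(3)
  n <- 12
  groups <- factor(rep(c("A", "B"), each = 6))
  covs <- data.frame(age = rnorm(n, 70, 5), tiv = rnorm(n, 1.4e6, 1e5))
  rms <- random_rate_maps(n)
  d1 <- make_design(groups, covs)
  d2 <- make_design(groups, data.frame(age = covs$age * 3 - 100,
                                       tiv = covs$tiv / 1e5 + 7))
  t1 <- fit_ancova(rms, d1, c(A = 1, B = -1), mask8)
  t2 <- fit_ancova(rms, d2, c(A = 1, B = -1), mask8)
  expect_equal(t1$data, t2$data, tolerance = 1e-8)
})

test_that("omnibus F equals t^2 for a two-group one-contrast design", {
  set.seed(4)
  n <- 10
  groups <- factor(rep(c("A", "B"), each = 5))
  rms <- random_rate_maps(n)
  design <- make_design(groups)
  tmap <- fit_ancova(rms, design, c(A = 1, B = -1), mask8)
  fmap <- fit_ancova(rms, design, matrix(c(1, -1), nrow = 1), mask8)
  expect_equal(fmap$data, tmap$data^2, tolerance = 1e-10)
  expect_equal(fmap$stat_kind, "F")
  expect_equal(fmap$df, c(1, n - 2))
})

test_that("rank-deficient designs name the collinear columns", {
  groups <- factor(rep(c("A", "B"), each = 4))
  covs <- data.frame(x1 = rep(c(1, 0), each = 4))  # aliased with group A
  expect_error(make_design(groups, covs), "collinear")
})

test_that("planted group contrast concentrates |t| inside the true network", {
  spec <- tiny_pipeline_spec(seed = 21L)
  coh <- generate_cohort(spec)
  rates <- cohort_rate_maps(coh, fwhm_mm = 6)
  mask <- full_mask(spec$grid_shape)
  design <- make_design(coh$covariates$group,
                        coh$covariates[, c("age", "sex", "education", "tiv")])
  sm <- fit_ancova(rates, design, c(MCIp = 1, MCIs = -1), mask)
  net <- coh$truth$true_network
  expect_gt(mean(abs(sm$data[net])), mean(abs(sm$data[!net])))
})
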