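test_that("smoothness estimation recovers an applied 3-voxel kernel", {
  set.seed(31)
  d <- c(48, 48, 48)
  maps <- lapply(1:3, function(i) {
    smooth_volume(array(rnorm(prod(d)), dim = d), 3)
  })
  est <- estimate_fwhm(maps, full_mask(d), voxel_size_mm = 1)
  expect_lt(abs(est$combined_fwhm_mm - 3) / 3, 0.15)
  expect_equal(est$combined_fwhm_mm, prod(est$fwhm_mm)^(1 / 3))
})

test_that("averaging identical residual maps is idempotent", {
  set.seed(32)
  m <- smooth_volume(array(rnorm(20^3), dim = c(20, 20, 20)), 2)
  e1 <- estimate_fwhm(list(m), full_mask(dim(m)))
  e2 <- estimate_fwhm(list(m, m), full_mask(dim(m)))
  expect_equal(e1$fwhm_mm, e2$fwhm_mm)
})

test_that("flat residuals are rejected", {
  m <- array(1, dim = c(8, 8, 8))
  expect_error(estimate_fwhm(list(m), full_mask(dim(m))), "flat residuals")
})

test_that("cluster labeling agrees with the flood-fill oracle", {
  set.seed(33)
  for (conn in c(6L, 18L, 26L)) {
    for (rep in 1:3) {
      x <- array(runif(7^3) < 0.25, dim = c(7, 7, 7))
      got <- label_clusters(x, conn)
      want <- oracle_label(x, conn)
      expect_identical(got, want)
    }
  }
})

test_that("degenerate alpha or no smoothing give the expected extents", {
  mask <- full_mask(c(32, 32, 32))
  suppressWarnings({
    thr1 <- simulate_cluster_threshold(0, mask, voxel_p = 0.005,
                                       cluster_alpha = 1.0, n_sim = 200,
                                       seed = 1)
    thr2 <- simulate_cluster_threshold(0, mask, voxel_p = 0.005,
                                       cluster_alpha = 0.05, n_sim = 400,
                                       seed = 2)
  })
  expect_equal(thr1$min_extent_voxels, 1L)
  expect_lte(thr2$min_extent_voxels, 5L)   # unsmoothed noise: isolated voxels
})

test_that("the extent threshold grows with smoothness", {
  mask <- full_mask(c(24, 24, 24))
  ok <- vapply(1:5, function(s) {
    suppressWarnings({
      lo <- simulate_cluster_threshold(1, mask, voxel_p = 0.005,
                                       n_sim = 300, seed = s)
      hi <- simulate_cluster_threshold(4, mask, voxel_p = 0.005,
                                       n_sim = 300, seed = s + 100)
    })
    hi$min_extent_voxels >= lo$min_extent_voxels
  }, TRUE)
  expect_gte(sum(ok), 4)
})

test_that("threshold simulation is deterministic under a fixed seed", {
  mask <- full_mask(c(16, 16, 16))
  suppressWarnings({
    a <- simulate_cluster_threshold(2, mask, n_sim = 150, seed = 7)
    b <- simulate_cluster_threshold(2, mask, n_sim = 150, seed = 7)
  })
  expect_identical(a$max_cluster_sizes, b$max_cluster_sizes)
  expect_identical(a$min_extent_voxels, b$min_extent_voxels)
})

fake_threshold <- function(min_extent, voxel_p = 0.005, connectivity = 18L) {
  structure(list(voxel_p = voxel_p, cluster_alpha = 0.05,
                 min_extent_voxels = min_extent, n_simulations = 0L,
                 fwhm_mm = rep(0, 3), connectivity = connectivity,
                 max_cluster_sizes = integer(0), seed = 0L),
            class = "cluster_threshold")
}

test_that("an all-zero map yields an empty cluster table", {
  zm <- stat_map(array(0, c(10, 10, 10)), "z", df = Inf,
                 mask = full_mask(c(10, 10, 10)))
  out <- apply_cluster_threshold(zm, fake_threshold(5L))
  expect_equal(nrow(out$clusters), 0)
  expect_false(any(out$mask))
})

test_that("a planted 600-voxel blob survives a 513-voxel extent threshold", {
  d <- c(20, 20, 20)
  z <- array(0, dim = d)
  blob <- which(array(TRUE, d))[1:600]   # contiguous scan-order block
  z[blob] <- 4
  zm <- stat_map(z, "z", df = Inf, mask = full_mask(d))
  out <- apply_cluster_threshold(zm, fake_threshold(513L, connectivity = 26L))
  expect_equal(nrow(out$clusters), 1)
  expect_equal(out$clusters$size, 600)
  expect_equal(sum(out$mask), 600)
})

test_that("surviving clusters equal the oracle labeling of the exceedance set", {
  set.seed(35)
  d <- c(9, 9, 9)
  z <- array(rnorm(prod(d)), dim = d) * 2
  zm <- stat_map(z, "z", df = Inf, mask = full_mask(d))
  thr <- fake_threshold(3L, voxel_p = 0.05)
  out <- apply_cluster_threshold(zm, thr)
  h <- qnorm(1 - 0.05 / 2)
  want_labs <- oracle_label(abs(z) > h, 18L)
  sizes <- tabulate(want_labs[want_labs > 0])
  want_mask <- array(want_labs > 0 & sizes[pmax(want_labs, 1)] >= 3, dim = d)
  expect_identical(out$mask, want_mask)
})

test_that("t maps are thresholded with the t height for their df", {
  d <- c(6, 6, 6)
  tm <- stat_map(array(3, d), "t", df = 10, mask = full_mask(d))
  # |t| = 3 exceeds the p<0.05 two-sided height (2.23) but not p<0.001 (4.59)
  out1 <- apply_cluster_threshold(tm, fake_threshold(1L, voxel_p = 0.05))
  out2 <- apply_cluster_threshold(tm, fake_threshold(1L, voxel_p = 0.001))
  expect_true(all(out1$mask))
  expect_false(any(out2$mask))
})
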