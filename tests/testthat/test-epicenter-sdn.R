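test_that("a 6-mm sphere on a 2-mm grid has 123 member voxels", {
  s <- sphere_seed(c(16, 16, 16), radius_mm = 6, voxel_size_mm = 2,
                   grid_shape = c(32, 32, 32))
  expect_equal(nrow(s$member_voxels), 123)
  expect_equal(oracle_sphere_count(3), 123)
})

test_that("sphere membership is symmetric under reflection about the center", {
  s <- sphere_seed(c(10, 10, 10), radius_mm = 5, voxel_size_mm = 1.5,
                   grid_shape = c(20, 20, 20))
  offs <- sweep(s$member_voxels, 2, c(10, 10, 10))
  reflected <- -offs
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  expect_identical(key(offs), key(reflected))
})

test_that("seeds are placed at cluster peaks with scan-order tie-breaking", {
  d <- c(16, 16, 16)
  z <- array(0, dim = d)
  z[8:12, 8:12, 8] <- 1
  z[10, 12, 8] <- 5
  zm <- stat_map(z, "z", df = Inf, mask = full_mask(d))
  thr <- structure(list(voxel_p = 0.5, cluster_alpha = 0.05,
                        min_extent_voxels = 2L, n_simulations = 0L,
                        fwhm_mm = rep(0, 3), connectivity = 18L,
                        max_cluster_sizes = integer(0), seed = 0L),
                   class = "cluster_threshold")
  out <- apply_cluster_threshold(zm, thr)
  seeds <- find_epicenters(zm, out, radius_mm = 3)
  expect_equal(length(seeds), 1)
  expect_equal(seeds[[1]]$center, c(10L, 12L, 8L))

  # two tied maxima: first in scan order wins
  z2 <- array(0, dim = d)
  z2[4, 4, 4] <- 3; z2[5, 4, 4] <- 3
  zm2 <- stat_map(z2, "z", df = Inf, mask = full_mask(d))
  out2 <- apply_cluster_threshold(zm2, thr)
  seeds2 <- find_epicenters(zm2, out2, radius_mm = 3)
  expect_equal(seeds2[[1]]$center, c(4L, 4L, 4L))

  empty <- apply_cluster_threshold(
    stat_map(array(0, d), "z", df = Inf, mask = full_mask(d)), thr)
  expect_error(find_epicenters(zm, empty), "no epicenters")
})

test_that("seed mean rates match trivial cases and the explicit-loop oracle", {
  d <- c(12, 12, 12)
  seed <- sphere_seed(c(6, 6, 6), radius_mm = 2.5, voxel_size_mm = 1,
                      grid_shape = d)
  expect_equal(extract_seed_rate(rate_map("a", array(-0.02, d)), seed), -0.02)

  half <- array(0, dim = d)
  half[seed$member_index[seq(1, nrow(seed$member_voxels), 2)]] <- 2
  n_mem <- nrow(seed$member_voxels)
  expect_equal(extract_seed_rate(rate_map("b", half), seed),
               2 * length(seq(1, n_mem, 2)) / n_mem)

  set.seed(41)
  rnd <- array(rnorm(prod(d)), dim = d)
  acc <- 0
  for (r in seq_len(n_mem)) {
    v <- seed$member_voxels[r, ]
    acc <- acc + rnd[v[1], v[2], v[3]]
  }
  expect_equal(extract_seed_rate(rate_map("c", rnd), seed), acc / n_mem,
               tolerance = 1e-12)
})

test_that("perfect seed-voxel coupling saturates the z map at that voxel", {
  set.seed(42)
  d <- c(8, 8, 8)
  n <- 12
  seed_vals <- rnorm(n)
  rms <- lapply(seq_len(n), function(i) {
    m <- array(rnorm(prod(d)), dim = d)
    m[3, 3, 3] <- seed_vals[i]          # this voxel equals the seed exactly
    rate_map(paste0("s", i), m)
  })
  sdn <- map_sdn(rms, seed_vals, covariates = NULL, mask = full_mask(d))
  expect_equal(sdn$zmap$data[3, 3, 3], 38)
  expect_error(map_sdn(rms, rep(1, n), NULL, full_mask(d)), "zero-variance")
})

test_that("SDN maps are invariant to shifting all seed values by a constant", {
  set.seed(43)
  d <- c(8, 8, 8)
  n <- 15
  rms <- random_rate_maps(n, d)
  vals <- rnorm(n)
  covs <- data.frame(age = rnorm(n))
  a <- map_sdn(rms, vals, covs, full_mask(d))
  b <- map_sdn(rms, vals + 5.7, covs, full_mask(d))
  expect_equal(a$zmap$data, b$zmap$data, tolerance = 1e-8)
})

test_that("seed coupling is calibrated when rates are independent of the seed", {
  set.seed(44)
  d <- c(16, 16, 16)
  n <- 40
  rms <- random_rate_maps(n, d)
  vals <- rnorm(n)
  sdn <- map_sdn(rms, vals, covariates = NULL, mask = full_mask(d))
  pvals <- 2 * pt(abs(sdn$tmap$data), df = sdn$tmap$df, lower.tail = FALSE)
  frac <- mean(pvals < 0.005)
  se <- sqrt(0.005 * 0.995 / prod(d))
  expect_lt(abs(frac - 0.005), 4 * se)
})

test_that("top-percent masks honor the boundary cases and the sort oracle", {
  set.seed(45)
  d <- c(6, 6, 6)
  mask <- full_mask(d)
  z <- array(rnorm(prod(d)), dim = d)
  zm <- stat_map(z, "z", df = Inf, mask = mask)

  expect_identical(top_percent_mask(zm, mask, 100)$data, mask$data)
  expect_error(top_percent_mask(zm, mask, 0), "percent")
  expect_error(top_percent_mask(zm, mask, 101), "percent")

  # 10 in-mask voxels, 10 percent, unique values -> the single argmax
  m10 <- array(FALSE, dim = d); m10[1:10] <- TRUE
  mask10 <- analysis_mask(m10)
  sel <- top_percent_mask(zm, mask10, 10)
  expect_equal(sum(sel$data), 1)
  expect_equal(which(sel$data), which.max(z[1:10]))

  # random map vs sort-based selection
  p <- 7
  sel2 <- top_percent_mask(zm, mask, p)
  n_keep <- ceiling(p / 100 * prod(d))
  want <- sort(order(-as.vector(z))[seq_len(n_keep)])
  expect_identical(which(sel2$data), want)
})

test_that("top-percent masks are nested and non-decreasing in size", {
  set.seed(46)
  d <- c(8, 8, 8)
  mask <- full_mask(d)
  z <- array(sample(rep(rnorm(64), 8)), dim = d)   # heavy ties
  zm <- stat_map(z, "z", df = Inf, mask = mask)
  masks <- lapply(1:10, function(p) top_percent_mask(zm, mask, p))
  sizes <- vapply(masks, function(m) m$size_voxels, 0L)
  expect_true(all(diff(sizes) >= 0))
  for (p in 1:9) {
    expect_true(all(masks[[p + 1]]$data[masks[[p]]$data]))
  }
  expect_equal(sizes, vapply(1:10, function(p) ceiling(p / 100 * prod(d)), 0))
})
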