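# Separable 3-D Gaussian smoothing with zero-padding boundary handling.
#
# Smoothing is implemented as three one-dimensional discrete convolutions,
# one per axis, each realized as a banded matrix product. Values beyond the
# grid are treated as zero (no boundary renormalization); constants are
# therefore preserved only away from the grid faces, which is the intended
# behaviour for whole-volume maps that are masked afterwards.

#' Convert Gaussian FWHM to standard deviation
#'
#' @param fwhm Full width at half maximum (any length unit).
#' @return Standard deviation in the same unit, `fwhm / (2 * sqrt(2 * log(2)))`.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' @rdname fwhm_to_sigma
#' @param sigma Gaussian standard deviation.
#' @export
sigma_to_fwhm <- function(sigma) sigma * (2 * sqrt(2 * log(2)))

# Normalized 1-D Gaussian kernel sampled at integer offsets, truncated at
# 4 sigma (at least +/-1 voxel).
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

# n x n zero-padded convolution matrix for a symmetric kernel.
conv_matrix_1d <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  m <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    m[cbind(i[ok], j[ok])] <- kernel[off + r + 1L]
  }
  m
}

#' Smooth a 3-D volume with an isotropic (or per-axis) Gaussian kernel
#'
#' Separable discrete Gaussian convolution with zero padding outside the
#' grid. A FWHM of 0 is the identity.
#'
#' @param x 3-D numeric array.
#' @param fwhm_mm Kernel FWHM in mm; scalar or length-3 (per axis).
#' @param voxel_size_mm Voxel edge length in mm (isotropic grids).
#' @return Smoothed array of the same dimensions.
#' @export
smooth_volume <- function(x, fwhm_mm, voxel_size_mm = 1) {
  if (length(dim(x)) != 3L) stopf("smooth_volume() expects a 3-D array")
  if (any(fwhm_mm < 0)) stopf("fwhm_mm must be non-negative")
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  if (all(fwhm_mm == 0)) return(x)
  d <- dim(x)
  sig <- fwhm_to_sigma(fwhm_mm) / voxel_size_mm
  kern <- lapply(sig, gaussian_kernel_1d)

  # axis 1
  if (length(kern[[1]]) > 1L) {
    m1 <- conv_matrix_1d(d[1], kern[[1]])
    x <- array(m1 %*% matrix(x, d[1], d[2] * d[3]), dim = d)
  }
  # axis 2
  if (length(kern[[2]]) > 1L) {
    m2 <- conv_matrix_1d(d[2], kern[[2]])
    xp <- aperm(x, c(2L, 1L, 3L))
    xp <- array(m2 %*% matrix(xp, d[2], d[1] * d[3]), dim = c(d[2], d[1], d[3]))
    x <- aperm(xp, c(2L, 1L, 3L))
  }
  # axis 3
  if (length(kern[[3]]) > 1L) {
    m3 <- conv_matrix_1d(d[3], kern[[3]])
    x <- array(matrix(x, d[1] * d[2], d[3]) %*% t(m3), dim = d)
  }
  x
}

# Interior standard-deviation shrinkage factor of unit white noise under the
# separable kernel: prod_axes sqrt(sum(k^2)). Used to rescale smoothed noise
# to a target marginal sd away from grid boundaries.
smoothing_sd_factor <- function(fwhm_mm, voxel_size_mm = 1) {
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  sig <- fwhm_to_sigma(fwhm_mm) / voxel_size_mm
  prod(vapply(sig, function(s) sqrt(sum(gaussian_kernel_1d(s)^2)), 0))
}

# Batch variant: smooth `n` stacked volumes (4-D array, last dim = field)
# with one banded-matrix product per axis. Identical per-field result to
# smooth_volume().
smooth_volumes_batch <- function(x, fwhm_mm, voxel_size_mm = 1) {
  d4 <- dim(x)
  stopifnot(length(d4) == 4L)
  d <- d4[1:3]; nf <- d4[4]
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  if (all(fwhm_mm == 0)) return(x)
  sig <- fwhm_to_sigma(fwhm_mm) / voxel_size_mm
  kern <- lapply(sig, gaussian_kernel_1d)
  if (length(kern[[1]]) > 1L) {
    m1 <- conv_matrix_1d(d[1], kern[[1]])
    x <- array(m1 %*% matrix(x, d[1], d[2] * d[3] * nf), dim = d4)
  }
  if (length(kern[[2]]) > 1L) {
    m2 <- conv_matrix_1d(d[2], kern[[2]])
    xp <- aperm(x, c(2L, 1L, 3L, 4L))
    xp <- array(m2 %*% matrix(xp, d[2], d[1] * d[3] * nf),
                dim = c(d[2], d[1], d[3], nf))
    x <- aperm(xp, c(2L, 1L, 3L, 4L))
  }
  if (length(kern[[3]]) > 1L) {
    m3 <- conv_matrix_1d(d[3], kern[[3]])
    xp <- aperm(x, c(3L, 1L, 2L, 4L))
    xp <- array(m3 %*% matrix(xp, d[3], d[1] * d[2] * nf),
                dim = c(d[3], d[1], d[2], nf))
    x <- aperm(xp, c(2L, 3L, 1L, 4L))
  }
  x
}

# n standardized smooth noise fields as a (n_mask x n) matrix of in-mask
# values, each standardized to mean 0 / sd 1 within the mask.
standardized_noise_matrix <- function(n, fwhm_mm, mask, voxel_size_mm = 1,
                                      chunk = 100L) {
  d <- dim(mask$data)
  inmask <- as.vector(mask$data)
  out <- matrix(0, sum(inmask), n)
  done <- 0L
  while (done < n) {
    k <- min(chunk, n - done)
    noise <- array(stats::rnorm(prod(d) * k), dim = c(d, k))
    noise <- smooth_volumes_batch(noise, fwhm_mm, voxel_size_mm)
    v <- matrix(noise, prod(d), k)[inmask, , drop = FALSE]
    v <- scale(v)   # per-field standardization within mask
    out[, done + seq_len(k)] <- v
    done <- done + k
  }
  out
}

#' Generate a spatially smooth Gaussian noise field
#'
#' White Gaussian noise smoothed to the requested FWHM and rescaled so the
#' interior marginal standard deviation equals `sd` (smoothing shrinks the
#' pointwise variance by a known kernel factor).
#'
#' @param grid_shape Length-3 integer vector of grid dimensions.
#' @param fwhm_mm Smoothness of the field, FWHM in mm (0 = white noise).
#' @param voxel_size_mm Voxel edge length in mm.
#' @param sd Target interior marginal standard deviation.
#' @return 3-D numeric array.
#' @export
smooth_noise_field <- function(grid_shape, fwhm_mm, voxel_size_mm = 1, sd = 1) {
  x <- array(stats::rnorm(prod(grid_shape)), dim = grid_shape)
  if (all(fwhm_mm == 0)) return(x * sd)
  x <- smooth_volume(x, fwhm_mm, voxel_size_mm)
  x * (sd / smoothing_sd_factor(fwhm_mm, voxel_size_mm))
}
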