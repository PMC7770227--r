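# Synthetic longitudinal cohort generator.
#
# Emulates the data layer the pipeline assumes: four diagnostic groups
# (HC, MCIs, MCIp, AD) scanned 2-3 times at roughly annual intervals, with
# per-voxel relative-volume maps near 1 that drift linearly at a per-subject,
# per-voxel annual rate. The rate field is
#
#   r_{v,i} = beta0_v + sum_k lambda_{k,v} * f_{k,i}
#             + sum_c gamma_{c,v} * z_{c,i} + eta_{v,i}
#
# with one latent atrophy factor f_k per planted network (group-graded mean,
# between-subject sd factor_sd), standardized nuisance covariates z, and a
# spatially smooth per-subject rate-heterogeneity field eta (individual
# variation in aging rate; without it one-sample statistics would be
# degenerate because out-of-network voxels would have no between-subject
# variance). Observed maps add spatially smooth acquisition noise per visit.
# Cognitive score slopes are linearly coupled to the subject's mean rate over
# the coupled network voxels.

GROUPS <- c("HC", "MCIs", "MCIp", "AD")

COG_TESTS <- c("MMSE", "CVVLT", "CFT_copy", "CFT_recall", "VFT", "BNT", "TMT_B")

# Typical memory-clinic covariate location/scale used to standardize
# covariates inside the generator (age years, sex 0/1, education years,
# total intracranial volume mm^3).
COV_CENTER <- c(age = 76, sex = 0.5, education = 12, tiv = 1.46e6)
COV_SCALE  <- c(age = 6,  sex = 0.5, education = 4,  tiv = 1.3e5)

# Baseline cognitive scores by test and group (typical memory-clinic means)
# and per-test between-subject intercept sd.
COG_BASELINES <- matrix(
  c(28.5, 27.2, 24.7, 20.7,
    7.79, 5.04, 3.50, 1.04,
    15.7, 15.4, 14.8, 15.0,
    11.5, 6.96, 4.58, 0.83,
    16.8, 12.7, 13.6, 12.3,
    28.2, 26.6, 24.5, 23.5,
    13.3, 11.4, 11.2, 8.59),
  nrow = 7, byrow = TRUE,
  dimnames = list(COG_TESTS, GROUPS)
)
COG_INTERCEPT_SD <- c(MMSE = 1.4, CVVLT = 1.3, CFT_copy = 1.6,
                      CFT_recall = 3.3, VFT = 3.9, BNT = 2.3, TMT_B = 2.3)

#' Specify a synthetic longitudinal cohort
#'
#' Builds and validates the parameter set for [generate_cohort()]. Defaults
#' describe a four-group memory-clinic style cohort (33/25/12/23 subjects)
#' on a 32^3 grid of 3-mm voxels with two planted epicenter-anchored
#' networks whose atrophy rates are graded by disease severity.
#'
#' @param grid_shape Length-3 integer grid dimensions (each >= 12).
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param n_per_group Named integer vector of group sizes (HC, MCIs, MCIp,
#'   AD); each >= 2.
#' @param n_timepoints Scans per subject, 2 or 3.
#' @param two_timepoint_fraction Fraction of subjects with only 2 scans
#'   (longitudinal attrition); remaining subjects have `n_timepoints`.
#' @param time_spacing_years Nominal inter-scan interval in years.
#' @param time_jitter_sd SD (years) of jitter on follow-up scan times; 0
#'   gives exact annual spacing.
#' @param epicenters List of length-3 voxel coordinates, one per planted
#'   network.
#' @param network_radius_vox Radius (voxels) of the planted network support
#'   around each epicenter; loadings are zero beyond it.
#' @param loading_core_vox Radius of the flat unit-loading core.
#' @param loading_shoulder_vox Gaussian decay scale of loadings between core
#'   and outer radius.
#' @param loading_maps Optional list of explicit per-network 3-D loading
#'   arrays (lambda_v >= 0); overrides the radial construction.
#' @param group_mean_rates Named vector (shared by all networks) or list of
#'   named vectors (one per network) of group mean latent atrophy factors,
#'   fractional volume change per year (negative = atrophy).
#' @param factor_sd Between-subject SD of each latent factor.
#' @param baseline_rate Scalar or 3-D array: per-voxel baseline rate beta0_v.
#' @param covariate_effects Named vector (or list of scalars/3-D arrays) of
#'   per-voxel rate slopes per SD of each covariate (age, sex, education,
#'   tiv).
#' @param rate_noise_sd Interior SD of the per-subject smooth
#'   rate-heterogeneity field eta (per year); 0 disables it.
#' @param noise_sd Interior SD of per-visit acquisition noise on the maps.
#' @param smoothing_fwhm_mm Spatial FWHM (mm) of both eta and the visit
#'   noise.
#' @param cognitive_coupling Named vector of per-test slopes b linking the
#'   mean coupled-network rate to the cognitive score slope (score units per
#'   unit rate).
#' @param coupled_networks Indices of networks whose union drives cognition
#'   (default: all).
#' @param cognitive_slope_sd Residual SD of the true cognitive slope
#'   (score/year); scalar or named per test.
#' @param cognitive_score_sd Per-visit measurement SD of scores.
#' @param seed Integer RNG seed; the whole cohort is a deterministic
#'   function of the spec.
#' @return An object of class `cohort_spec`.
#' @seealso [cohort_preset()] for the shipped presets.
#' @export
cohort_spec <- function(grid_shape = c(32L, 32L, 32L),
                        voxel_size_mm = 3,
                        n_per_group = c(HC = 33L, MCIs = 25L, MCIp = 12L, AD = 23L),
                        n_timepoints = 3L,
                        two_timepoint_fraction = 17 / 93,
                        time_spacing_years = 1,
                        time_jitter_sd = 0,
                        epicenters = list(c(9L, 12L, 16L), c(23L, 20L, 16L)),
                        network_radius_vox = 3.5,
                        loading_core_vox = 0,
                        loading_shoulder_vox = 3,
                        loading_maps = NULL,
                        group_mean_rates = c(HC = -0.004, MCIs = -0.008,
                                             MCIp = -0.028, AD = -0.036),
                        factor_sd = 0.008,
                        baseline_rate = -0.004,
                        covariate_effects = c(age = -4e-4, sex = 2e-4,
                                              education = 3e-4, tiv = 0),
                        rate_noise_sd = 0.0065,
                        noise_sd = 0.008,
                        smoothing_fwhm_mm = 6,
                        cognitive_coupling = c(MMSE = 50, CVVLT = 40,
                                               CFT_copy = 0, CFT_recall = 40,
                                               VFT = 40, BNT = 30, TMT_B = 25),
                        coupled_networks = NULL,
                        cognitive_slope_sd = 0.6,
                        cognitive_score_sd = 0.3,
                        seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 12L)) {
    stopf("grid_shape must be three integers, each >= 12")
  }
  if (voxel_size_mm <= 0) stopf("voxel_size_mm must be positive")
  if (!all(GROUPS %in% names(n_per_group))) {
    stopf("n_per_group must name all of: %s", paste(GROUPS, collapse = ", "))
  }
  n_per_group <- as.integer(n_per_group[GROUPS])
  names(n_per_group) <- GROUPS
  if (any(n_per_group < 2L)) stopf("each group needs at least 2 subjects")
  n_timepoints <- as.integer(n_timepoints)
  if (!n_timepoints %in% 2:3) stopf("n_timepoints must be 2 or 3")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (rate_noise_sd < 0) stopf("rate_noise_sd must be non-negative")
  if (factor_sd < 0) stopf("factor_sd must be non-negative")
  if (smoothing_fwhm_mm < 0) stopf("smoothing_fwhm_mm must be non-negative")

  n_networks <- if (!is.null(loading_maps)) length(loading_maps) else length(epicenters)
  if (is.list(group_mean_rates)) {
    if (length(group_mean_rates) != n_networks) {
      stopf("group_mean_rates list must have one element per network")
    }
    rate_list <- lapply(group_mean_rates, function(g) g[GROUPS])
  } else {
    rate_list <- rep(list(group_mean_rates[GROUPS]), n_networks)
  }
  if (n_networks > 0 && any(vapply(rate_list, anyNA, TRUE))) {
    stopf("group_mean_rates must name all groups")
  }
  if (!is.null(loading_maps)) {
    for (lm in loading_maps) {
      if (!identical(as.integer(dim(lm)), grid_shape)) {
        stopf("loading_maps must match grid_shape")
      }
      if (any(lm < 0)) stopf("network loadings must be non-negative")
    }
  }
  if (!all(names(COV_CENTER) %in% names(covariate_effects))) {
    stopf("covariate_effects must name: %s", paste(names(COV_CENTER), collapse = ", "))
  }
  cognitive_coupling <- cognitive_coupling[COG_TESTS]
  cognitive_coupling[is.na(cognitive_coupling)] <- 0
  names(cognitive_coupling) <- COG_TESTS
  if (length(cognitive_slope_sd) == 1L && is.null(names(cognitive_slope_sd))) {
    cognitive_slope_sd <- stats::setNames(rep(cognitive_slope_sd, 7L), COG_TESTS)
  } else {
    cognitive_slope_sd <- cognitive_slope_sd[COG_TESTS]
    stopifnot(!anyNA(cognitive_slope_sd))
  }
  coupled_networks <- coupled_networks %||% seq_len(n_networks)

  spec <- structure(list(
    grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
    n_per_group = n_per_group, n_timepoints = n_timepoints,
    two_timepoint_fraction = two_timepoint_fraction,
    time_spacing_years = time_spacing_years, time_jitter_sd = time_jitter_sd,
    epicenters = epicenters, network_radius_vox = network_radius_vox,
    loading_core_vox = loading_core_vox,
    loading_shoulder_vox = loading_shoulder_vox,
    loading_maps = loading_maps, group_mean_rates = rate_list,
    factor_sd = factor_sd, baseline_rate = baseline_rate,
    covariate_effects = covariate_effects, rate_noise_sd = rate_noise_sd,
    noise_sd = noise_sd, smoothing_fwhm_mm = smoothing_fwhm_mm,
    cognitive_coupling = cognitive_coupling,
    coupled_networks = coupled_networks,
    cognitive_slope_sd = cognitive_slope_sd,
    cognitive_score_sd = cognitive_score_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")

  flat_baseline <- all(unlist(baseline_rate) == 0)
  flat_covariates <- all(vapply(covariate_effects,
                                function(g) all(unlist(g) == 0), TRUE))
  degenerate <- spec$noise_sd <= 0 && spec$rate_noise_sd <= 0 &&
    flat_baseline && flat_covariates &&
    (n_networks == 0 ||
       (all(vapply(rate_list, function(g) all(g == g[1]), TRUE)) &&
          spec$factor_sd == 0))
  if (degenerate) warnf("degenerate cohort spec: no signal and no noise")
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec\n")
  cat(sprintf("  grid: %s voxels of %g mm; %d networks\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_size_mm,
              n_networks(x)))
  cat(sprintf("  subjects: %s (total %d), %d timepoints\n",
              paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                    collapse = " "),
              sum(x$n_per_group), x$n_timepoints))
  invisible(x)
}

n_networks <- function(spec) {
  if (!is.null(spec$loading_maps)) length(spec$loading_maps) else length(spec$epicenters)
}

# Radial loading profile: flat unit core, Gaussian shoulder, hard zero
# beyond the outer radius. Returns a 3-D array.
radial_loading_map <- function(grid_shape, center, radius_vox, core_vox,
                               shoulder_vox) {
  d <- grid_shape
  dx <- (seq_len(d[1]) - center[1])^2
  dy <- (seq_len(d[2]) - center[2])^2
  dz <- (seq_len(d[3]) - center[3])^2
  dist <- sqrt(outer(outer(dx, dy, "+"), dz, "+"))
  lam <- ifelse(dist <= core_vox, 1,
                exp(-(dist - core_vox)^2 / (2 * shoulder_vox^2)))
  lam[dist > radius_vox] <- 0
  array(lam, dim = d)
}

cohort_loading_maps <- function(spec) {
  if (!is.null(spec$loading_maps)) return(spec$loading_maps)
  lapply(spec$epicenters, function(ctr) {
    radial_loading_map(spec$grid_shape, ctr, spec$network_radius_vox,
                       spec$loading_core_vox, spec$loading_shoulder_vox)
  })
}

#' Shipped cohort presets
#'
#' * `"graded"` — the default spec: two planted networks with
#'   severity-graded atrophy and cognitive coupling to their union.
#' * `"null"` — pure noise: no networks, zero baseline rate, zero covariate
#'   and cognitive effects, unsmoothed visit noise. Used for statistical
#'   calibration.
#' * `"association"` — one severity-graded network coupled to cognition with
#'   the residual slope SD chosen analytically so the model-implied Spearman
#'   correlation between network atrophy rate and cognitive slope is 0.40,
#'   plus one uncoupled decoy network with group-independent atrophy.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
cohort_preset <- function(name = c("graded", "null", "association"), ...) {
  name <- match.arg(name)
  over <- list(...)
  args <- switch(name,
    graded = list(),
    null = list(
      epicenters = list(),
      group_mean_rates = c(HC = 0, MCIs = 0, MCIp = 0, AD = 0),
      baseline_rate = 0,
      covariate_effects = c(age = 0, sex = 0, education = 0, tiv = 0),
      rate_noise_sd = 0,
      smoothing_fwhm_mm = 0,
      two_timepoint_fraction = 0,
      cognitive_coupling = c(MMSE = 0, CVVLT = 0, CFT_copy = 0,
                             CFT_recall = 0, VFT = 0, BNT = 0, TMT_B = 0)
    ),
    association = list(
      group_mean_rates = list(
        c(HC = -0.004, MCIs = -0.008, MCIp = -0.028, AD = -0.036),
        c(HC = -0.016, MCIs = -0.016, MCIp = -0.016, AD = -0.016)
      ),
      coupled_networks = 1L,
      two_timepoint_fraction = 0,
      cognitive_score_sd = 0.1,
      cognitive_coupling = c(MMSE = 50, CVVLT = 50, CFT_copy = 0,
                             CFT_recall = 50, VFT = 50, BNT = 50, TMT_B = 50)
    )
  )
  args[names(over)] <- over
  spec <- do.call(cohort_spec, args)
  if (name == "association" && !("cognitive_slope_sd" %in% names(over))) {
    spec$cognitive_slope_sd <- tuned_slope_sd(spec, target_spearman = 0.4)
  }
  spec
}

# Residual SD of the cognitive slope such that the model-implied Spearman
# correlation between the coupled-network mean rate and the cognitive slope
# equals target_spearman. Under bivariate normality Spearman rho_s maps to
# Pearson rho via rho = 2*sin(pi*rho_s/6). Signal variance of the network
# mean rate combines the latent factor (between-group + within-group) with
# the exact variance of the averaged smooth heterogeneity field; the
# covariate contribution is excluded because the analysis partials it out.
tuned_slope_sd <- function(spec, target_spearman = 0.4) {
  loads <- cohort_loading_maps(spec)
  k <- spec$coupled_networks
  member <- Reduce(`|`, lapply(loads[k], function(l) l > 0))
  n_mem <- sum(member)
  lam_bar <- vapply(loads[k], function(l) sum(l[member]) / n_mem, 0)

  w <- spec$n_per_group / sum(spec$n_per_group)
  var_f <- vapply(spec$group_mean_rates[k], function(mu) {
    m <- sum(w * mu)
    sum(w * (mu - m)^2) + spec$factor_sd^2
  }, 0)
  var_signal <- sum(lam_bar^2 * var_f)

  if (spec$rate_noise_sd > 0) {
    ind <- array(0, dim = spec$grid_shape)
    ind[member] <- 1
    sm <- smooth_volume(ind, spec$smoothing_fwhm_mm, spec$voxel_size_mm)
    fac <- smoothing_sd_factor(spec$smoothing_fwhm_mm, spec$voxel_size_mm)
    var_signal <- var_signal +
      (spec$rate_noise_sd / fac)^2 * sum(sm^2) / n_mem^2
  }

  rho_p <- 2 * sin(pi * target_spearman / 6)
  b <- spec$cognitive_coupling
  sds <- b * sqrt(var_signal) * sqrt(1 / rho_p^2 - 1)
  sds[b == 0] <- 0.6
  sds
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws covariates, latent network atrophy factors, per-subject rate
#' fields, serial volumetric maps and serial cognitive scores according to a
#' [cohort_spec()]. Bitwise deterministic in the spec (including its seed).
#'
#' @param spec A `cohort_spec`.
#' @return An object of class `sdn_cohort`: a list with elements
#'   `subjects` (list of `subject_series`), `covariates` (data frame:
#'   subject_id, group, age, sex, education, tiv), `cognition` (long data
#'   frame: subject_id, test, time, score), `truth` (ground truth: latent
#'   factors, true per-subject rate matrix, per-network loading maps and
#'   member sets, epicenters, per-subject coupled-network mean rate, true
#'   cognitive slopes) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  d <- spec$grid_shape
  nvox <- prod(d)
  n <- sum(spec$n_per_group)
  groups <- factor(rep(GROUPS, spec$n_per_group), levels = GROUPS)
  ids <- sprintf("S%03d", seq_len(n))

  covariates <- data.frame(
    subject_id = ids,
    group = groups,
    age = stats::rnorm(n, COV_CENTER["age"], COV_SCALE["age"]),
    sex = stats::rbinom(n, 1L, 0.5),
    education = stats::rnorm(n, COV_CENTER["education"], COV_SCALE["education"]),
    tiv = stats::rnorm(n, COV_CENTER["tiv"], COV_SCALE["tiv"]),
    stringsAsFactors = FALSE
  )
  zcov <- scale(as.matrix(covariates[, names(COV_CENTER)]),
                center = COV_CENTER, scale = COV_SCALE)

  loads <- cohort_loading_maps(spec)
  nk <- length(loads)
  factors <- matrix(0, n, nk)
  if (nk > 0) {
    for (k in seq_len(nk)) {
      mu <- spec$group_mean_rates[[k]][as.character(groups)]
      factors[, k] <- stats::rnorm(n, mu, spec$factor_sd)
    }
  }

  # per-subject scan counts and times
  n_tp <- rep(spec$n_timepoints, n)
  if (spec$two_timepoint_fraction > 0 && spec$n_timepoints > 2L) {
    n2 <- round(spec$two_timepoint_fraction * n)
    if (n2 > 0) n_tp[sample.int(n, n2)] <- 2L
  }
  times <- lapply(seq_len(n), function(i) {
    tt <- (seq_len(n_tp[i]) - 1) * spec$time_spacing_years
    if (spec$time_jitter_sd > 0 && n_tp[i] > 1L) {
      tt[-1] <- tt[-1] + stats::rnorm(n_tp[i] - 1L, 0, spec$time_jitter_sd)
      tt <- sort(tt)
    }
    tt
  })

  # deterministic rate components
  beta0 <- if (length(spec$baseline_rate) == 1L) {
    rep(spec$baseline_rate, nvox)
  } else as.vector(spec$baseline_rate)
  gam <- lapply(names(COV_CENTER), function(cn) {
    g <- spec$covariate_effects[[cn]]
    if (length(g) == 1L) rep(as.numeric(g), nvox) else as.vector(g)
  })
  names(gam) <- names(COV_CENTER)

  rates <- matrix(rep(beta0, n), nrow = n, byrow = TRUE)
  if (nk > 0) {
    for (k in seq_len(nk)) {
      rates <- rates + factors[, k, drop = FALSE] %*% t(as.vector(loads[[k]]))
    }
  }
  for (cn in names(gam)) {
    rates <- rates + zcov[, cn, drop = FALSE] %*% t(gam[[cn]])
  }

  # subject maps: smooth heterogeneity field + per-visit smooth noise
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    if (spec$rate_noise_sd > 0) {
      eta <- smooth_noise_field(d, spec$smoothing_fwhm_mm, spec$voxel_size_mm,
                                sd = spec$rate_noise_sd)
      rates[i, ] <- rates[i, ] + as.vector(eta)
    }
    r_i <- array(rates[i, ], dim = d)
    maps <- lapply(times[[i]], function(tt) {
      eps <- if (spec$noise_sd > 0) {
        smooth_noise_field(d, spec$smoothing_fwhm_mm, spec$voxel_size_mm,
                           sd = spec$noise_sd)
      } else 0
      1 + r_i * tt + eps
    })
    subjects[[i]] <- subject_series(
      subject_id = ids[i], group = as.character(groups[i]),
      covariates = covariates[i, c("age", "sex", "education", "tiv")],
      times = times[[i]], maps = maps, voxel_size_mm = spec$voxel_size_mm
    )
  }

  # cognition: slope coupled to mean rate over the coupled network union
  member_union <- if (nk > 0 && length(spec$coupled_networks) > 0) {
    Reduce(`|`, lapply(loads[spec$coupled_networks], function(l) l > 0))
  } else array(FALSE, dim = d)
  netrate <- if (any(member_union)) {
    rowMeans(rates[, as.vector(member_union), drop = FALSE])
  } else rep(0, n)

  slopes_true <- matrix(0, n, length(COG_TESTS),
                        dimnames = list(ids, COG_TESTS))
  cog <- vector("list", n * length(COG_TESTS))
  idx <- 1L
  for (i in seq_len(n)) {
    for (test in COG_TESTS) {
      b <- spec$cognitive_coupling[[test]]
      sl <- b * netrate[i] +
        stats::rnorm(1L, 0, spec$cognitive_slope_sd[[test]])
      slopes_true[i, test] <- sl
      icpt <- COG_BASELINES[test, as.character(groups[i])] +
        stats::rnorm(1L, 0, COG_INTERCEPT_SD[[test]])
      sc <- icpt + sl * times[[i]] +
        stats::rnorm(n_tp[i], 0, spec$cognitive_score_sd)
      cog[[idx]] <- data.frame(subject_id = ids[i], test = test,
                               time = times[[i]], score = sc,
                               stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  cognition <- do.call(rbind, cog)
  rownames(cognition) <- NULL

  truth <- list(
    factors = factors,
    rates = rates,
    loading_maps = loads,
    true_networks = lapply(loads, function(l) l > 0),
    true_network = member_union,
    epicenters = spec$epicenters,
    netrate = netrate,
    cognitive_slopes = slopes_true
  )
  structure(list(subjects = subjects, covariates = covariates,
                 cognition = cognition, truth = truth, spec = spec),
            class = "sdn_cohort")
}

#' @export
print.sdn_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, grid %s, %d planted network(s)\n",
              length(x$subjects), paste(x$spec$grid_shape, collapse = "x"),
              length(x$truth$loading_maps)))
  invisible(x)
}

#' One subject's serial volumetric map series
#'
#' @param subject_id Subject identifier.
#' @param group Group label (HC, MCIs, MCIp, AD).
#' @param covariates One-row data frame with age, sex, education, tiv.
#' @param times Acquisition times in years from baseline, strictly
#'   increasing, length >= 2.
#' @param maps List of 3-D arrays (relative volume scale), one per time.
#' @param voxel_size_mm Voxel edge length in mm.
#' @return An object of class `subject_series`.
#' @export
subject_series <- function(subject_id, group, covariates, times, maps,
                           voxel_size_mm = 1) {
  if (length(times) != length(maps) || length(times) < 2L) {
    stopf("need matching times and maps, at least 2 of each")
  }
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  d <- dim(maps[[1]])
  for (m in maps) assert_same_grid(maps[[1]], m)
  structure(list(subject_id = subject_id, group = group,
                 covariates = covariates, times = times, maps = maps,
                 voxel_size_mm = voxel_size_mm, grid_shape = d),
            class = "subject_series")
}

#' @export
print.subject_series <- function(x, ...) {
  cat(sprintf("subject_series %s (%s): %d maps at years %s\n", x$subject_id,
              x$group, length(x$maps),
              paste(signif(x$times, 3), collapse = ", ")))
  invisible(x)
}
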