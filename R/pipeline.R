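# End-to-end orchestration: rate maps -> group contrast + epicenters ->
# SDN mapping in controls -> group degeneration patterns -> permutation
# similarity -> GOF network preference -> cognitive association.

#' Pipeline configuration
#'
#' Defaults follow the conventional settings of this analysis family:
#' 8-mm rate-map smoothing, 0.2 mask threshold, voxel p < 0.005 with
#' cluster-FWE alpha 0.05, 6-mm seed spheres, 1,000 permutations, GOF at
#' the top 1-10 percent, Bonferroni over 6 domain tests.
#'
#' @param fwhm_mm Rate-map smoothing FWHM in mm.
#' @param mask_threshold Tissue mask threshold (used only when tissue maps
#'   are supplied).
#' @param voxel_p Voxel-level two-sided p threshold.
#' @param cluster_alpha Cluster-extent familywise alpha.
#' @param seed_radius_mm Epicenter seed sphere radius in mm.
#' @param n_perm Permutations for spatial similarity.
#' @param gof_percents Fixed-size GOF percentages.
#' @param bonferroni_n Number of corrected domain tests.
#' @param n_sim_cluster Monte-Carlo simulations for the extent threshold.
#' @param connectivity Cluster connectivity (6/18/26).
#' @param epicenter_contrast Named contrast identifying epicenters
#'   (default MCIp - MCIs).
#' @param atrophy_sign Multiplier mapping atrophy to positive z in group
#'   degeneration maps (-1 because rates are negative under atrophy).
#' @param sdn_direction Binarization direction for SDN masks.
#' @param reuse_cluster_threshold Reuse the group-contrast extent threshold
#'   for SDN binarization instead of re-simulating per seed (saves time;
#'   smoothness is typically near-identical because the residuals share the
#'   same acquisition noise).
#' @param seed Master RNG seed for all stochastic stages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fwhm_mm = 8, mask_threshold = 0.2,
                            voxel_p = 0.005, cluster_alpha = 0.05,
                            seed_radius_mm = 6, n_perm = 1000L,
                            gof_percents = 1:10, bonferroni_n = 6L,
                            n_sim_cluster = 1000L, connectivity = 18L,
                            epicenter_contrast = c(MCIp = 1, MCIs = -1),
                            atrophy_sign = -1,
                            sdn_direction = "positive",
                            reuse_cluster_threshold = TRUE,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full SDN pipeline on a cohort
#'
#' Executes, in order: per-subject rate maps (slope + smoothing); the
#' epicenter group contrast with cluster-FWE thresholding and seed
#' placement; seed-based SDN mapping and binarization in the control
#' group; one-sample group degeneration z maps; smoothness-matched
#' permutation similarity between each SDN and each group map; GOF network
#' preference (thresholded and fixed-size); and the partial-Spearman
#' cognitive association over the mean rate of the binarized SDNs.
#'
#' @param cohort An `sdn_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, statistic maps (NIfTI),
#'   result tables (TSV) and the run manifest (JSON) are written there.
#' @return An object of class `sdn_pipeline` with all stage outputs and a
#'   `manifest` sufficient to reproduce the run.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cohort, "sdn_cohort"), inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  covnames <- c("age", "sex", "education", "tiv")
  cov_all <- cohort$covariates
  if (!all(covnames %in% names(cov_all))) {
    stopf("pipeline stage 'glm' failed: covariate table lacks columns %s",
          paste(setdiff(covnames, names(cov_all)), collapse = ", "))
  }
  groups <- factor(cov_all$group, levels = GROUPS)
  vs <- cohort$subjects[[1]]$voxel_size_mm

  # A: rate maps and mask
  rates <- stage("rate_maps", cohort_rate_maps(cohort, config$fwhm_mm))
  mask <- stage("mask", full_mask(cohort$subjects[[1]]$grid_shape))

  # B: epicenter contrast, smoothness, extent threshold, seeds
  design <- stage("glm", make_design(groups, cov_all[, covnames]))
  contrast_map <- stage("glm", fit_ancova(rates, design,
                                          config$epicenter_contrast, mask,
                                          keep_residuals = TRUE))
  resid <- attr(contrast_map, "residuals")
  smoothness <- stage("smoothness",
                      estimate_fwhm(residual_maps(resid, mask), mask, vs))
  thr <- stage("cluster_sim", simulate_cluster_threshold(
    smoothness, mask, vs, config$voxel_p, config$cluster_alpha,
    config$n_sim_cluster, seed = derive_seed(config$seed, 1L),
    connectivity = config$connectivity))
  thresholded <- stage("cluster_threshold",
                       apply_cluster_threshold(contrast_map, thr))
  seeds <- stage("epicenters",
                 find_epicenters(contrast_map, thresholded,
                                 config$seed_radius_mm, mask))

  # C: SDNs in the control group
  hc <- groups == "HC"
  hc_rates <- rates[hc]
  hc_cov <- cov_all[hc, covnames]
  sdns <- list()
  sdn_masks <- list()
  sdn_smoothness <- list()
  for (k in seq_along(seeds)) {
    seed_vals <- vapply(hc_rates, extract_seed_rate, 0, seed = seeds[[k]])
    sdn <- stage("sdn", map_sdn(hc_rates, seed_vals, hc_cov, mask,
                                seed = seeds[[k]]))
    sm_k <- stage("sdn", estimate_fwhm(residual_maps(sdn$residuals, mask),
                                       mask, vs))
    thr_k <- if (config$reuse_cluster_threshold) thr else {
      stage("sdn", simulate_cluster_threshold(
        sm_k, mask, vs, config$voxel_p, config$cluster_alpha,
        config$n_sim_cluster, seed = derive_seed(config$seed, 10L + k),
        connectivity = config$connectivity))
    }
    # a seed whose coupling map survives nowhere yields no network; it is
    # recorded as empty and excluded from network-level summaries
    sdn_masks[k] <- list(tryCatch(
      sdn_network_mask(sdn, thr_k, config$sdn_direction),
      error = function(e) {
        warnf("SDN %d: %s", k, conditionMessage(e))
        NULL
      }))
    sdn_smoothness[[k]] <- sm_k
    sdns[[k]] <- sdn
  }

  # D: group degeneration z maps (atrophy mapped to positive z)
  patient_groups <- c("MCIs", "MCIp", "AD")
  group_z <- lapply(patient_groups, function(g) {
    sel <- groups == g
    zm <- stage("one_sample", t_to_z(fit_one_sample(rates[sel],
                                                    cov_all[sel, covnames],
                                                    mask)))
    zm$data <- config$atrophy_sign * zm$data
    zm$contrast <- sprintf("%s atrophy (sign %+d)", g, config$atrophy_sign)
    zm
  })
  names(group_z) <- patient_groups

  # E: permutation spatial similarity (n_perm = 0 skips the stage)
  similarity <- list()
  for (k in if (config$n_perm > 0) seq_along(sdns) else integer(0)) {
    similarity[[k]] <- lapply(seq_along(patient_groups), function(g) {
      stage("similarity", permutation_similarity(
        sdns[[k]]$zmap, group_z[[g]], mask, sdn_smoothness[[k]], vs,
        n_perm = config$n_perm,
        seed = derive_seed(config$seed, 100L + 10L * k + g)))
    })
    names(similarity[[k]]) <- patient_groups
  }

  # F: GOF preference and cognitive association
  gof_tables <- lapply(seq_along(sdns), function(k) {
    if (is.null(sdn_masks[[k]])) return(NULL)
    do.call(rbind, lapply(patient_groups, function(g) {
      gg <- stage("gof", gof(sdn_masks[[k]], group_z[[g]], mask))
      data.frame(sdn = k, group = g, gof = gg$gof,
                 mean_z_inside = gg$mean_z_inside,
                 mean_z_outside = gg$mean_z_outside)
    }))
  })
  gof_profiles <- lapply(seq_along(sdns), function(k) {
    do.call(rbind, lapply(patient_groups, function(g) {
      pr <- stage("gof", gof_profile(sdns[[k]]$zmap, group_z[[g]], mask,
                                     config$gof_percents))
      cbind(sdn = k, group = g, pr)
    }))
  })

  kept_masks <- Filter(Negate(is.null), sdn_masks)
  if (length(kept_masks) == 0L) {
    stopf("pipeline stage 'sdn' failed: no SDN survived the cluster threshold")
  }
  sdn_union <- Reduce(`|`, lapply(kept_masks, function(m) m$data))
  mean_sdn_rate <- vapply(rates, function(r) mean(r$data[sdn_union]), 0)
  slopes <- stage("cognition", cognitive_slopes(cohort$cognition))
  slopes <- slopes[match(cov_all$subject_id, slopes$subject_id), ]
  cognition <- do.call(rbind, lapply(COG_TESTS, function(test) {
    pc <- stage("cognition", partial_spearman(mean_sdn_rate, slopes[[test]],
                                              cov_all[, covnames]))
    data.frame(test = test, rho = pc$rho, p = pc$p, n = pc$n)
  }))
  cognition <- bonferroni_annotate(cognition, n_tests = config$bonferroni_n)

  manifest <- list(
    package_version = as.character(utils::packageVersion("sdnmap")),
    config = unclass(config),
    n_subjects = length(cohort$subjects),
    grid_shape = cohort$subjects[[1]]$grid_shape,
    voxel_size_mm = vs,
    n_epicenters = length(seeds),
    stage_seeds = list(cluster_sim = derive_seed(config$seed, 1L)),
    cohort_seed = if (!is.null(cohort$spec)) cohort$spec$seed else NA
  )

  result <- structure(list(
    rates = rates, mask = mask, design = design,
    contrast_map = contrast_map, smoothness = smoothness,
    cluster_threshold = thr, thresholded = thresholded, seeds = seeds,
    sdns = sdns, sdn_masks = sdn_masks, sdn_smoothness = sdn_smoothness,
    group_z = group_z, similarity = similarity,
    gof = gof_tables, gof_profiles = gof_profiles,
    mean_sdn_rate = mean_sdn_rate, cognitive_slopes = slopes,
    cognition = cognition, manifest = manifest, config = config
  ), class = "sdn_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.sdn_pipeline <- function(x, ...) {
  cat(sprintf("sdn_pipeline: %d epicenter(s), extent threshold %d voxels\n",
              length(x$seeds), x$cluster_threshold$min_extent_voxels))
  for (k in seq_along(x$seeds)) {
    nv <- if (is.null(x$sdn_masks[[k]])) "no surviving" else
      x$sdn_masks[[k]]$size_voxels
    cat(sprintf("  SDN %d at (%s): %s network voxels\n", k,
                paste(x$seeds[[k]]$center, collapse = ","), nv))
  }
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vs <- result$contrast_map$voxel_size_mm
  write_volume(result$contrast_map, file.path(out_dir, "contrast_t.nii.gz"), vs)
  for (k in seq_along(result$sdns)) {
    write_volume(result$sdns[[k]]$zmap,
                 file.path(out_dir, sprintf("sdn%d_z.nii.gz", k)), vs)
    if (!is.null(result$sdn_masks[[k]])) {
      write_volume(result$sdn_masks[[k]]$data * 1,
                   file.path(out_dir, sprintf("sdn%d_mask.nii.gz", k)), vs)
    }
  }
  for (g in names(result$group_z)) {
    write_volume(result$group_z[[g]],
                 file.path(out_dir, sprintf("group_%s_z.nii.gz", g)), vs)
  }
  write_tsv(result$thresholded$clusters, file.path(out_dir, "clusters.tsv"))
  write_tsv(do.call(rbind, result$gof), file.path(out_dir, "gof.tsv"))
  write_tsv(do.call(rbind, result$gof_profiles),
            file.path(out_dir, "gof_profiles.tsv"))
  write_tsv(result$cognition, file.path(out_dir, "cognition.tsv"))
  sim <- do.call(rbind, lapply(seq_along(result$similarity), function(k) {
    do.call(rbind, lapply(names(result$similarity[[k]]), function(g) {
      s <- result$similarity[[k]][[g]]
      data.frame(sdn = k, group = g, r = s$r_observed, p_perm = s$p_perm,
                 n_perm = s$n_perm)
    }))
  }))
  write_tsv(sim, file.path(out_dir, "similarity.tsv"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Score pipeline output against a synthetic cohort's ground truth
#'
#' Matches each planted epicenter to the nearest identified seed and
#' reports: the voxel distance per planted epicenter, the Dice overlap of
#' each matched SDN mask with its planted network, and whether the GOF of
#' the first SDN is ordered MCIs < MCIp <= AD.
#'
#' @param pipeline An `sdn_pipeline`.
#' @param cohort The generating `sdn_cohort` (must carry `truth`).
#' @return List with `epicenter_distance_vox`, `dice`, `gof_by_group`,
#'   `gof_ordered`.
#' @export
evaluate_recovery <- function(pipeline, cohort) {
  tr <- cohort$truth
  if (is.null(tr)) stopf("cohort carries no ground truth")
  found <- t(vapply(pipeline$seeds, function(s) as.numeric(s$center),
                    numeric(3)))
  planted <- tr$epicenters
  match_k <- integer(length(planted))
  dist_vox <- numeric(length(planted))
  for (j in seq_along(planted)) {
    dd <- sqrt(colSums((t(found) - as.numeric(planted[[j]]))^2))
    match_k[j] <- which.min(dd)
    dist_vox[j] <- min(dd)
  }
  dice <- vapply(seq_along(planted), function(j) {
    m <- pipeline$sdn_masks[[match_k[j]]]
    if (is.null(m)) 0 else dice_overlap(m$data, tr$true_networks[[j]])
  }, 0)
  g1 <- pipeline$gof[[match_k[1]]]
  if (is.null(g1)) {
    gofs <- stats::setNames(rep(NA_real_, 3), c("MCIs", "MCIp", "AD"))
    ordered <- FALSE
  } else {
    gofs <- stats::setNames(g1$gof, g1$group)
    ordered <- gofs["MCIs"] < gofs["MCIp"] && gofs["MCIp"] <= gofs["AD"]
  }
  list(epicenter_distance_vox = dist_vox, matched_seed = match_k,
       dice = dice, gof_by_group = gofs, gof_ordered = unname(ordered))
}
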