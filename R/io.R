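# On-disk formats: NIfTI-1 for maps, TSV for tables, JSON for ground truth
# and reports, YAML for configuration.

#' Write a 3-D map as NIfTI-1
#'
#' @param data 3-D array (or `rate_map`/`stat_map`).
#' @param file Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel edge length in mm, stored in the header.
#' @return The path, invisibly.
#' @export
write_volume <- function(data, file, voxel_size_mm = 1) {
  vs <- voxel_size_mm
  if (inherits(data, "rate_map") || inherits(data, "stat_map")) {
    vs <- data$voxel_size_mm
    data <- data$data
  }
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- rep(vs, 3L)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a NIfTI-1 volume
#'
#' @param file Path to a `.nii`/`.nii.gz` file.
#' @return List with `data` (3-D array) and `voxel_size_mm`.
#' @export
read_volume <- function(file) {
  img <- RNifti::readNifti(file)
  list(data = array(as.numeric(img), dim = dim(img)),
       voxel_size_mm = RNifti::pixdim(img)[1])
}

#' Write a synthetic cohort to a directory
#'
#' Layout: `maps/<subject>_tp<k>.nii.gz` per subject-timepoint,
#' `scans.tsv` (subject_id, timepoint, time_years, file), `covariates.tsv`,
#' `cognition.tsv`, and `truth.json` (epicenters, true-network voxel
#' indices, latent factors, per-subject network rates and true cognitive
#' slopes).
#'
#' @param cohort An `sdn_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sdn_cohort"))
  dir.create(file.path(dir, "maps"), recursive = TRUE, showWarnings = FALSE)
  scans <- list()
  for (s in cohort$subjects) {
    for (k in seq_along(s$maps)) {
      f <- file.path("maps", sprintf("%s_tp%d.nii.gz", s$subject_id, k))
      write_volume(s$maps[[k]], file.path(dir, f), s$voxel_size_mm)
      scans[[length(scans) + 1L]] <- data.frame(
        subject_id = s$subject_id, group = s$group, timepoint = k,
        time_years = s$times[k], file = f, stringsAsFactors = FALSE)
    }
  }
  write_tsv(do.call(rbind, scans), file.path(dir, "scans.tsv"))
  write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"))
  write_tsv(cohort$cognition, file.path(dir, "cognition.tsv"))
  tr <- cohort$truth
  sidecar <- list(
    grid_shape = cohort$spec$grid_shape,
    voxel_size_mm = cohort$spec$voxel_size_mm,
    epicenters = tr$epicenters,
    true_network_index = which(tr$true_network),
    true_network_index_per_network = lapply(tr$true_networks, which),
    factors = tr$factors,
    netrate = tr$netrate,
    cognitive_slopes = tr$cognitive_slopes,
    seed = cohort$spec$seed
  )
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return An `sdn_cohort` without ground-truth rate matrices (only the
#'   sidecar summary under `truth`).
#' @export
read_cohort <- function(dir) {
  scans <- read_tsv(file.path(dir, "scans.tsv"))
  covariates <- read_tsv(file.path(dir, "covariates.tsv"))
  covariates$group <- factor(covariates$group, levels = GROUPS)
  cognition <- read_tsv(file.path(dir, "cognition.tsv"))
  subjects <- lapply(split(scans, scans$subject_id), function(df) {
    df <- df[order(df$timepoint), ]
    vols <- lapply(df$file, function(f) read_volume(file.path(dir, f)))
    covrow <- covariates[covariates$subject_id == df$subject_id[1],
                         c("age", "sex", "education", "tiv")]
    subject_series(df$subject_id[1], df$group[1], covrow,
                   times = df$time_years,
                   maps = lapply(vols, `[[`, "data"),
                   voxel_size_mm = vols[[1]]$voxel_size_mm)
  })
  subjects <- subjects[order(match(names(subjects), covariates$subject_id))]
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  structure(list(subjects = unname(subjects), covariates = covariates,
                 cognition = cognition, truth = truth, spec = NULL),
            class = "sdn_cohort")
}

write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(file) {
  if (!file.exists(file)) stopf("missing table: %s", file)
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}
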