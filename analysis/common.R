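# Shared helpers for the numbered analysis scripts. Each script is a thin
# driver over the sdnmap package; heavy intermediates are cached under
# scratch/ (disposable), tables land under results/.

library(sdnmap)

ANALYSIS_SEED <- 20260929L

paths <- list(scratch = "scratch", results = "results")
for (p in paths) dir.create(p, recursive = TRUE, showWarnings = FALSE)

analysis_spec <- function() cohort_spec(seed = ANALYSIS_SEED)

analysis_config <- function() {
  pipeline_config(seed = ANALYSIS_SEED + 1L, n_perm = 1000L,
                  n_sim_cluster = 2000L)
}

load_or_make_cohort <- function() {
  f <- file.path(paths$scratch, "cohort.rds")
  if (file.exists(f)) return(readRDS(f))
  coh <- generate_cohort(analysis_spec())
  saveRDS(coh, f)
  coh
}

load_or_run_pipeline <- function(cohort = load_or_make_cohort()) {
  f <- file.path(paths$scratch, "pipeline.rds")
  if (file.exists(f)) return(readRDS(f))
  pl <- run_pipeline(cohort, analysis_config())
  saveRDS(pl, f)
  pl
}

write_result <- function(df, name) {
  f <- file.path(paths$results, name)
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", f)
  invisible(f)
}
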