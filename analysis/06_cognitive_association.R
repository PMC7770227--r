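#!/usr/bin/env Rscript
# Partial Spearman correlation between the mean atrophy rate of the
# binarized SDNs and per-subject cognitive decline slopes, Bonferroni
# corrected over the six domain tests (MMSE judged separately).

source("analysis/common.R")

coh <- load_or_make_cohort()
pl <- load_or_run_pipeline(coh)

tbl <- pl$cognition
tbl$rho <- signif(tbl$rho, 3)
tbl$p <- signif(tbl$p, 4)
cat("Cognitive association (partial Spearman, n = ", tbl$n[1], "):\n", sep = "")
print(tbl, row.names = FALSE)
write_result(tbl, "06_cognition.tsv")

sig <- tbl$test[tbl$significant]
cat(sprintf("\nSignificant after correction: %s\n",
            if (length(sig)) paste(sig, collapse = ", ") else "none"))
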