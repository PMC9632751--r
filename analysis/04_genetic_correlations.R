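#!/usr/bin/env Rscript
# Stage 4 — bivariate fits: genetic/phenotypic/environmental correlations,
# correlated responses and indirect-selection efficiencies for all trait
# pairs, plus per-pond parent EBV summaries.

library(shrimpquant)

dat <- "results/data"
rep_ <- run_report(file.path(dat, "traits.csv"), file.path(dat, "pedigree.csv"),
                   "results", ebv_trait = "BL")
cat("Trait-pair correlation table:\n")
print(utils::head(rep_$correlations, 12))
cat("... written to results/report_correlations.csv\n")
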