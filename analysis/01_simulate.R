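#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study population.
#
# No raw data accompany the study design this pipeline emulates, so every
# downstream stage runs on a simulated population built to the published
# design: 5,308 offspring of 64 sires and 54 dams in 76 full/half-sib
# families, reared in eight ponds, with trait (co)variances taken from the
# published genetic-parameter tables. Writes pedigree, phenotype, landmark
# and truth files under results/data/.

library(shrimpquant)

out <- "results/data"
cfg <- sim_config(seed = 20260930)
ds <- run_simulate(cfg, out, landmarks = TRUE)

cat("Simulated", nrow(ds$phenotypes), "offspring in",
    length(unique(ds$phenotypes$pond)), "ponds;",
    nrow(ds$families), "families.\n")
cat("Files written to", out, "\n")
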