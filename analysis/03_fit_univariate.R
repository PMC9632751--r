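#!/usr/bin/env Rscript
# Stage 3 — univariate animal-model REML per trait.
#
# Fits y = pond + animal + residual for each derived trait, sharing one
# spectral decomposition of the relationship matrix across traits, and
# writes variance components, heritabilities and per-animal EBVs for body
# length (the worked example used throughout).

library(shrimpquant)

dat <- "results/data"
fits <- run_fit(file.path(dat, "traits.csv"), file.path(dat, "pedigree.csv"),
                "results", ebv_traits = "BL")
comp <- read.csv("results/fit_components.csv")
print(comp[, c("trait", "sigmaA2", "sigmaE2", "h2", "h2_se", "converged")],
      digits = 3)
cat("Moderately heritable growth traits and low-h2 shape ratios are the",
    "expected pattern for derived traits whose genetic signal enters via",
    "the size and shape latents.\n")
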