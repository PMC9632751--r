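#!/usr/bin/env Rscript
# Stage 2 — landmark geometry to morphometric traits.
#
# Converts each animal's 12 landmark coordinates into the 66 pairwise
# distances and the ten derived size/shape traits (BL, BS, HS, AS, AP, TT,
# FBR, CF, CFL plus recorded BW), and summarises the shape space with a PCA
# of the distance matrix.

library(shrimpquant)

dat <- "results/data"
traits <- run_derive(file.path(dat, "landmarks.csv"),
                     file.path(dat, "phenotypes.csv"),
                     file.path(dat, "traits.csv"))

lms <- read_landmarks(file.path(dat, "landmarks.csv"))
D <- t(vapply(lms, pairwise_distances, numeric(66)))
pca <- run_pca(D)
ve <- round(100 * pca$variance_explained[1:5], 1)
cat("PCA of the 66 distances: first five components explain",
    paste0(ve, "%", collapse = ", "), "\n")
write.csv(data.frame(component = seq_along(pca$variance_explained),
                     variance_explained = pca$variance_explained),
          "results/pca_variance.csv", row.names = FALSE)
cat("Trait table:", nrow(traits), "animals.\n")
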