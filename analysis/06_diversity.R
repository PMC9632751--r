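#!/usr/bin/env Rscript
# Stage 6 — family diversity within and between ponds.
#
# Shannon-Wiener index per pond (sire- and dam-families separately) measures
# evenness of family representation; Morisita-Horn overlap between pond
# pairs measures similarity of family composition.

library(shrimpquant)

dat <- "results/data"
rep_ <- run_diversity(file.path(dat, "traits.csv"),
                      file.path(dat, "pedigree.csv"), "results")
print(rep_$shannon, digits = 3)
mh <- rep_$mh$sire
lo <- which(mh == min(mh[lower.tri(mh)]), arr.ind = TRUE)[1, ]
cat(sprintf("Least-overlapping ponds (sire families): %s vs %s, MH = %.2f\n",
            rownames(mh)[lo[1]], colnames(mh)[lo[2]], min(mh[lower.tri(mh)])))
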