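# shrimpquant

Quantitative genetic evaluation of image-derived morphometric traits in
farmed shrimp (*Penaeus monodon*).

Growth is what most shrimp breeding programs select on, but the *shape* of
the animal — head versus abdominal proportions, condition, tail size —
determines meat yield and market value, and is awkward to measure on a
curved-bodied crustacean. Twelve landmarks digitised from a photograph give a
workable route: pairwise distances, body-segment areas and ratio traits that
can be fed into a standard pedigree-based genetic evaluation. This package
implements that chain end to end, for breeders and quantitative geneticists:

* **Morphometry** — 66 canonical pairwise landmark distances; Heron-formula
  segment areas (head `S0` through tail `S4`); derived traits `BL`, `BS`,
  `HS`, `AS`, `AP`, `TT`, `FBR`, `CF`, `CFL`; PCA of the distance matrix.
* **Pedigree** — validated, topologically sorted pedigrees; the additive
  relationship matrix **A** by the tabular method, cross-checked by a
  gene-dropping Monte-Carlo estimator.
* **Animal model REML** — univariate and bivariate fits of
  `y = Xb + Za + e`, `cov(a) = sigmaA2 * A`, by average-information updates
  with an exact (monotone) EM fallback; a spectral formulation makes every
  iteration O(n) after one eigendecomposition. Heritabilities with
  delta-method SEs, BLUP breeding values with reliabilities.
* **G×E** — the genetic correlation of the same trait across pond pairs
  (structural-zero residual covariance; non-estimable pairs reported as
  missing, high-SE pairs flagged).
* **Selection response** — correlated response `CR_y = rg * h_x * h_y` and
  relative efficiency of indirect selection `%IS = 100 * rg * h_x / h_y`.
* **Family diversity** — Shannon-Wiener evenness per pond and Morisita-Horn
  overlap between ponds, for sire- and dam-families.
* **Simulator** — complete datasets (pedigree, pond allocation, multi-trait
  phenotypes, landmarks) with known genetic architecture at the study scale:
  5,308 offspring of 64 sires and 54 dams, 76 families, eight ponds, with
  published trait (co)variances as the default truth, and an optional true
  cross-pond genetic correlation for G×E studies.

## Worked example

Simulate a study-scale population, derive traits from the generated
landmarks, and fit the animal model per trait (this is exactly what
`analysis/01...03` do):

```r
library(shrimpquant)

cfg <- sim_config(seed = 20260930)      # 5,308 offspring, 8 ponds, 76 families
run_simulate(cfg, "results/data", landmarks = TRUE)
run_derive("results/data/landmarks.csv", "results/data/phenotypes.csv",
           "results/data/traits.csv")
run_fit("results/data/traits.csv", "results/data/pedigree.csv", "results",
        ebv_traits = "BL")
read.csv("results/fit_components.csv")[, c("trait", "sigmaA2", "sigmaE2", "h2", "h2_se")]
```

```
   trait sigmaA2 sigmaE2    h2  h2_se
1     BW 5.00427 8.99784 0.357 0.0531
2     BL 0.37003 0.59604 0.383 0.0557
3     BS 2.28482 3.71953 0.381 0.0555
4     HS 0.29665 0.47600 0.384 0.0558
5     AS 0.93513 1.54593 0.377 0.0551
6     AP 0.00696 0.21930 0.031 0.0097
7     TT 0.00293 0.00610 0.325 0.0497
8    FBR 0.00001 0.00030 0.029 0.0095
9     CF 0.00054 0.01036 0.050 0.0130
10   CFL 0.00007 0.00700 0.010 0.0059
```

Growth-related traits (`BW`, `BL`, areas, `TT`) come out moderately heritable
(h² ≈ 0.32–0.38, each within two standard errors of its simulated truth),
while the shape ratios (`AP`, `FBR`, `CF`, `CFL`) are lowly heritable — the
pattern a breeder would read as "select directly on growth, use family
information for shape". The selection-response calculators then quantify
indirect gains, e.g. with published inputs (rg = 0.36 between body weight and
abdominal percentage, h² = 0.32 and 0.09):

```r
correlated_response(0.36, 0.32, 0.09)   # 0.061 phenotypic SDs of AP
relative_efficiency(0.99, 0.32, 0.31)   # 100.6% -> indirect selection on HS
                                        # via BW is as good as direct
```

The remaining drivers (`analysis/04...07`) produce the trait-pair
correlation table with CR and %IS columns, the cross-pond G×E tables for
`BW`/`BL` (mean cross-pond rg ≈ 0.94 under the default no-G×E simulation:
no family re-ranking between ponds), the per-pond family-diversity tables,
and the worked selection-response table from the published parameter
estimates.

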