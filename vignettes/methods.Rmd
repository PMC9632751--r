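---
title: "Quantitative genetics of image-derived shrimp morphometrics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of image-derived shrimp morphometrics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(shrimpquant)
```

## The problem

Body weight is the usual selection target in shrimp breeding, but the shape of
the animal — head versus abdominal proportions, condition, tail size — matters
to yield and market value and is hard to measure directly on a curved-bodied
crustacean. Landmark coordinates digitised from photographs give a practical
route: twelve labelled points along the body outline yield pairwise distances,
segment areas and ratio traits that can be put through a standard quantitative
genetic evaluation. This package implements that full chain on *Penaeus
monodon*-style data: geometry to traits, pedigree to relationship matrix,
animal-model REML to variance components, and the derived quantities a breeder
acts on (heritabilities, genetic correlations, breeding values, correlated
responses, cross-pond genotype-by-environment correlations, family-diversity
diagnostics).

No raw dataset accompanies the design this package emulates, so a first-class
simulator generates populations with known genetic architecture at the study
scale — 5,308 offspring of 64 sires and 54 dams in 76 full/half-sib families
across eight grow-out ponds — and every pipeline stage is validated by
parameter recovery against that known truth.

## Landmark geometry

The twelve landmarks are one anterior point (`A1`), four dorsal points
(`D1`–`D4`), five ventral points (`V1`–`V5`) and two posterior tail points
(`PT`, `PB`). From a validated configuration the package computes:

* the 66 pairwise Euclidean distances, in a fixed lexicographic label-pair
  order so distance vectors round-trip through files;
* five body segment areas from quadrilaterals bounded by successive
  dorsal/ventral landmark pairs — `S0` the head (`A1, D1, V2, V1`) through
  `S4` the tail (`D4, PT, PB, V5`). The ventral chain has one extra anterior
  landmark, so dorsal `Di` pairs with ventral `V(i+1)`. Each quadrilateral is
  split along the diagonal from its anterior-dorsal vertex into two triangles
  whose Heron areas are summed. For convex outlines the five areas add up to
  the shoelace area of the whole outline polygon, which is the geometric
  oracle used in the tests (1,000 random convex outlines, 1e-9 relative
  tolerance). Self-intersecting quadrilaterals are a warning, not an error,
  and the area is computed from the two triangles as-is.
* the derived traits: body length `BL` from `A1` to the midpoint of `PT` and
  `PB` (the farther of the two is available behind `bl_endpoint = "max"`),
  tail tip `TT = |PT - PB|`, head size `HS = S0`, abdominal size
  `AS = S1 + ... + S4`, body size `BS = HS + AS`, abdominal percentage
  `AP = 100 AS / BS`, front-back ratio `FBR = (S0 + S1) / (S2 + S3 + S4)`,
  condition factor `CF = 100 BW / BL^3` and its length analogue
  `CFL = 100 BS / BL^2`.

The anatomical identity of each landmark and the exact triangulation are not
fully pinned down by the published description; the five-quadrilateral scheme
above is this package's documented canonical choice, fixed so that `FBR`
contrasts "head plus first abdominal segment" against "abdominal segments
two to four". Heron's formula clamps radicands within `1e-12 * s^4` of zero
(floating-point cancellation on near-degenerate triangles) and errors on
genuine triangle-inequality violations.

PCA of the distance matrix goes through `prcomp` with centred, unstandardised
columns by default (`scale.` is exposed; whether the original analysis
standardised the 66 distances is unstated). Component signs are fixed so each
component's largest-magnitude loading is positive.

## Pedigree and relationship matrix

`build_A()` implements the recursive tabular method, giving the additive
(numerator) relationship matrix **A** with diagonal `1 + F`. Storage is dense,
which is comfortable up to roughly 10,000 animals; a sparse `A`-inverse via
the usual founder/non-founder rules is a possible future optimisation but was
not needed at this scale. The method is validated against an independent
gene-dropping Monte-Carlo estimator (`gene_drop_A()`): founders receive unique
alleles, Mendelian transmission is simulated, and relationship is estimated
as twice the identity-by-descent probability of randomly drawn alleles —
50,000 replicates agree with the tabular matrix to within 0.01 on a
200-animal pedigree. Arbitrary group-assigned parent identifiers are treated
as ordinary unrelated founders.

## The animal model and REML

Every trait is analysed under

y = X beta + Z a + e,    a ~ N(0, sigmaA2 * A),    e ~ N(0, sigmaE2 * I),

with pond (eight levels) as the only fixed effect, matching the source design
(no maternal or common-environment terms). Heritability is
`sigmaA2 / (sigmaA2 + sigmaE2)`.

**Univariate fits** use a spectral formulation: with `M = A` restricted to the
phenotyped animals and `M = U D U'`, rotating the data by `U'` makes the
marginal covariance diagonal, so after one eigendecomposition every REML
iteration is O(n). Average-information (AI) updates with step-halving are the
default; an exact EM step — monotone in the restricted likelihood by
construction — is the fallback when the AI step fails, and `algorithm = "em"`
forces pure EM (the test suite asserts the non-decreasing likelihood trace).
Convergence requires a relative parameter change below `tol` (default 1e-8)
*and* a log-likelihood change below 1e-6; variances are floored at
`1e-10` times the phenotypic variance; a constant response returns both
components at the floor. Standard errors come from the inverse AI matrix at
the optimum, and the heritability SE by the delta method. Starting values are
half the phenotypic variance for each component.

**Bivariate fits** come in two forms. Trait pairs measured on the same
animals use the same spectral rotation with 2×2 blocks per eigenvalue
(`d_i G + R`), estimating full 2×2 genetic and residual covariance matrices —
this keeps 45 trait-pair fits cheap even at n = 5,308 because the single
eigendecomposition is shared. Cross-pond fits (the same trait in two ponds,
disjoint animal sets) cannot share a rotation, so a dense-V AI engine is used;
the residual covariance is fixed at zero because no animal is ever measured
in two ponds (a structural zero, not an estimate). If an iterate leaves the
parameter space, G (and R) are projected to the nearest PSD matrix
(eigenvalue floor) and the fit is flagged; when neither the AI step nor a
damped ascent step can improve the likelihood the fit is declared converged
at a constrained (boundary) optimum — this is the normal exit when the true
genetic correlation is 1.

Genetic, phenotypic and environmental correlations are covariances over
geometric-mean variances, with delta-method SEs from the AI covariance;
estimates are clipped to [-1, 1] with a flag. BLUP breeding values are
`sigmaA2 * A[, obs] P y` at the REML estimates, which propagates EBVs to
unphenotyped relatives (a non-phenotyped offspring of two phenotyped parents
receives exactly the parental average; the tests assert this). Prediction
error variances and reliabilities use the same projections. Per-pond parent
EBVs come from refitting the univariate model within each pond — whether the
original per-pond EBVs came from per-pond or joint fits is unstated; per-pond
refits are this package's documented choice.

## Genotype-by-environment interaction

G×E is quantified as the genetic correlation of the same trait expressed in
two ponds: values near 1 mean no family re-ranking across environments.
`gxe_matrix()` fits all pond pairs, seeds each fit from per-pond univariate
components, declares pairs linked by fewer than two sires non-estimable
(reported as missing, never forced), and flags estimates whose SE exceeds 0.3
— pairs with so little family overlap carry no usable information about G×E
either way.

## Family diversity

The Shannon-Wiener index (natural log, zero counts excluded) summarises
evenness of family representation within a pond, separately for sire- and
dam-families; the Morisita-Horn index (computed on the union of family keys)
summarises overlap of family composition between ponds, 0 = disjoint,
1 = identical. Both are elementary and authored directly; `vegan::diversity`
serves as an independent oracle in the tests.

## Selection response

The correlated response in trait *y* to a one-phenotypic-SD selection
differential in trait *x* is `CR_y = rg * h_x * h_y * SD_y`. The published
table tabulates the standardised form (`SD_y = 1`), and that is the package
default, with `sd_y` exposed for trait units. The relative efficiency of
indirect selection is `%IS = 100 * rg * h_x / h_y`; of the two printed
expressions for %IS this is the one that reproduces the published column, and
it reduces exactly to `100 * rg` at equal heritabilities. A handful of
published cells (e.g. body-weight to body-length %IS = 105) do not reproduce
from their own printed inputs under either expression — those cells are
excluded from exact checks; all verified cells are asserted at printed
precision.

## The simulator

`sim_config()` defaults encode the study conditions: 5,308 offspring, 64
sires, 54 dams, 76 families (each dam mated to at most two sires), eight
ponds. The 10-trait genetic and residual covariance matrices are assembled
from the published variance components and correlations; pairs without a
published estimate get zero covariance, and each matrix is projected to the
nearest PSD matrix with its diagonal restored. Published trait means are
added so phenotypes sit on a realistic positive scale, and rare Gaussian-tail
values of strictly positive traits are floored at 1% of the trait mean, with
the shift absorbed into the stored residual so the bookkeeping identity
`phenotype = fixed + BV + residual` stays exact.

Breeding values are drawn with covariance `G (x) A` through a Cholesky factor
of **A** (eigendecomposition fallback at the PSD boundary). Pond effects
default to deterministic shifts spreading pond means over one phenotypic SD
per trait (no magnitudes are published; this is a package choice, exposed in
the config). Family-to-pond allocation draws each family's pond proportions
from a symmetric Dirichlet; the default concentration of 0.5 produces the
markedly uneven family representation reported for commercial ponds, and the
concentration is exposed end to end. In G×E mode each pond expresses
`sqrt(rg) * common + sqrt(1 - rg) * pond-specific` breeding values, so the
true cross-pond genetic correlation is exactly `rg`.

Landmarks are generated from a fixed convex template whose derived traits
match the published means (BL 10.82 cm, HS 4.83 cm², AS 8.56 cm², AP ~64%,
FBR ~0.84); the one compromise is the tail-tip width (~0.96 cm against the
published 1.17 cm mean), the price of keeping every outline vertex convex
with margin. Each animal's template is scaled by its simulated `BL` and its
widths rebalanced smoothly (exponent profile from +1 at the head to -1 at the
tail) by its simulated `FBR`, then jittered with SD 0.001 of body length
(roughly 0.1 mm of digitisation noise — kept small so jittered outlines stay
convex; draws that break convexity are regenerated up to ten times). Derived
`BL` correlates > 0.99 with the generating size latent; `FBR` correlates more
weakly (~0.6) because the jitter acts on the small `S1` segment, which is a
realistic feature of ratio traits. A single integer seed drives all stages
through a fixed label-hash seed-splitting scheme, making every dataset
byte-reproducible from `(config, seed)`.

What the simulator does *not* emulate: growth over time, non-Gaussian trait
distributions, measurement operators beyond landmark jitter, genotypes, and
maternal/common-environment variance. Passing recovery tests therefore show
the estimation machinery is correct under the stated model, not that the
model captures every feature of real pond data.

## Problem sizes and numerical choices in the test suite

The validation suite was sized as follows, as package design choices: the
REML recovery study uses 50 replicates of n = 2,000 offspring (60 sires, 50
dams, 8 ponds) over one fixed mating design and allocation, redrawing genetic
and residual effects per replicate so a single eigendecomposition serves all
fits; the G×E recovery study runs at the full default scale (n = 5,308),
where each pond pair carries the family overlap the original cohort had —
at smaller n the one-sided sampling error at the `rg = 1` boundary dominates
the all-pairs mean; gene dropping uses 50,000 replicates on a 200-animal
pedigree; the geometry oracle uses 1,000 random convex outlines built by
pushing the template through random affine maps. The pipeline's G×E step
defaults to representative growth traits (`BW`, `BL`) because each pond-pair
fit is a dense REML solve; any trait subset can be requested.

## Known limitations

* Dense **A** and dense cross-pond V limit practical scale to roughly 10⁴
  animals; sparse inverse-A MME would lift this.
* Cross-pond fits near the `rg = 1` boundary report delta-method SEs, which
  are crude at a constrained optimum; profile-likelihood intervals would be
  better calibrated.
* The landmark template is one fixed body plan; allometric shape change with
  size (beyond the FBR latent) is not modelled, and Procrustes-style shape
  analysis is deliberately out of scope.
* EM fallback is exact (monotone) for the spectral engines; the dense
  cross-pond engine falls back to damped ascent instead, which is why its
  convergence flag distinguishes boundary optima.
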