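Package: shrimpquant
Title: Quantitative Genetics of Image-Derived Shrimp Morphometric Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genetic evaluation of landmark-derived size and shape
    traits in farmed shrimp (Penaeus monodon). Converts 12-point landmark
    configurations into pairwise morphometric distances and derived traits (body
    length, segment areas, condition factors and shape ratios), builds the
    pedigree numerator relationship matrix, fits univariate and bivariate animal
    models by REML (average-information updates with an exact EM fallback) to
    estimate heritabilities, genetic correlations and breeding values, quantifies
    genotype-by-environment interaction as cross-pond genetic correlations,
    summarises family diversity (Shannon-Wiener, Morisita-Horn), predicts
    correlated selection responses, and simulates complete datasets with known
    genetic architecture for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
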