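Package: tagsel
Title: Trait-Assisted and Multi-Trait Genomic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic selection (GBLUP) toolkit for a low-heritability focal
    trait aided by correlated secondary traits. Implements the two-stage
    analysis used in field-trial genomic prediction: a first-stage spatial
    mixed model with block effects and separable AR(1)xAR(1) residual
    correlation over field rows and columns yielding genotype adjusted means,
    and second-stage univariate and bivariate GBLUP with REML variance
    components, missing-record (trait-assisted) prediction, genomic
    heritability and genetic correlations. Includes the VanRaden realized
    relationship matrix with marker QC, five cross-validation selection
    strategies (standard, indirect, multi-trait indirect, multi-trait,
    trait-assisted), coincidence indices, expected selection accuracies, a
    training-fraction sweep, and a synthetic-data generator with the
    statistical structure (heritabilities, genetic correlations, spatial
    field layouts) the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
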