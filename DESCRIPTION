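Package: nociomics
Title: Discriminant Metabolomics, Lipidomics and Calcium-Imaging Analysis for Tissue-Injury Pain Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for burn-injury lipid-mediator studies: canonical
    variates discriminant ranking of paired longitudinal LC-MS feature tables,
    a lipidomics quality-control/normalisation/univariate pipeline with adduct
    annotation, ratiometric calcium-imaging response calling with viability
    gating, Arrhenius-based heat-threshold estimation with Gaussian multi-peak
    population decomposition, and exact contingency statistics for responder
    proportions. Includes synthetic-data generators with known ground truth so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
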