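Package: climqtl
Title: QTL Mapping for Performance and Climate Responsiveness in
    Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of doubled-haploid multi-environment
    field trials for mapping quantitative trait loci (QTL) that act on
    trait performance (stable marker effects across environments) and on
    responsiveness to climatic covariates (marker-by-environment-covariate
    interactions). Provides a factor-analytic multi-environment linear
    mixed model with separable AR1xAR1 spatial residuals fitted by
    average-information REML, degree-day phenology covariates, whole-genome
    scans with leave-one-chromosome-out genomic relationship matrices,
    Li-Ji multiple-testing thresholds, pruning and joint final QTL models,
    and classification of loci into a performance-by-responsiveness
    adaptation framework. A seeded synthetic-data generator covers
    partially replicated designs, biparental doubled-haploid genotypes and
    temperature series so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
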