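Package: rarelocus
Title: Rare-Variant Association Analysis for Targeted Re-Sequencing of
    Founder-Population Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for targeted re-sequencing association
    studies of quantitative metabolic traits in bottlenecked founder
    populations. Provides a synthetic cohort generator emulating a
    Finnish-style allele-frequency spectrum, consensus variant calling
    from replicate call sets with validation bookkeeping, site-frequency
    spectrum projection and nucleotide-diversity estimators,
    single-variant and conditional association tests with genotype
    principal components, gene-level rare-variant tests (weighted burden
    with permutation p-values and a variance-component score test with
    asymptotic p-values), greedy BIC multivariate model selection with
    variance-explained accounting, and FDR/Bonferroni multiplicity
    control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
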