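Package: plasticome
Title: Transcriptome Plasticity Analysis for Multi-Environment Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting phenotypic plasticity in multi-site,
    multi-stage expression studies of a single genotype, modelled on berry
    ripening trials of a grapevine clone grown in many vineyards. Implements
    a sample-name codec and expression-table I/O, replicate averaging and
    veraison (onset-of-ripening) normalization, unimodal gene selection by a
    k-means intensity sweep with Sarle's bimodality coefficient,
    permutation-based Significance Analysis of Microarrays (SAM),
    Kruskal-Wallis screening for environmentally plastic genes and
    factor-associated genes, Pearson-distance dendrograms and profile
    k-means, unit-variance PCA and OPLS-DA with cross-validated Q2 and
    permutation overfitting validation, developmental-marker and
    constitutive reference-gene selection, and a synthetic-data generator
    that plants known gene classes for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
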