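Package: methylage
Title: Epigenetic Age Prediction from DNA-Methylation Beta Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for building and applying small CpG-based epigenetic
    age predictors from Illumina Infinium beta-value matrices. Screens CpG
    sites for age-associated methylation by template matching (per-CpG
    Pearson correlation against a scaled donor-age template), selects a
    compact signature using combined-cohort correlation, per-dataset
    consistency and methylation dynamic range, fits per-CpG linear
    calibrations of beta against age, and predicts donor age by classical
    inverse regression averaged over the signature CpGs. Ships the published
    five-CpG aging signature (TRIM58, KCNQ1DN, NPTX2, GRIA2, BIRC4BP) and a
    synthetic multi-dataset cohort generator with planted age-associated
    CpGs so the whole workflow is testable without any array download.
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
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
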