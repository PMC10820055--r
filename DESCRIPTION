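Package: scaffqsar
Title: Scaffold-Aware QSAR Modelling of Ion-Channel Modulator Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantitative structure-activity
    relationship (QSAR) regression on bioactivity endpoints (pKi, pIC50,
    pEC50). Covers activity-table curation (unit conversion to negative log
    molar, salt stripping, duplicate merging), four molecular descriptor
    families (MACCS keys, path-based hashed fingerprints, Morgan/ECFP4
    circular fingerprints, electrotopological-state descriptors),
    carbon-scaffold (cyclic skeleton) train/test splitting, recursive
    feature elimination driven by random-forest importance, four regression
    learners under grid search, five-fold cross-validation and external
    validation, Y-randomization, and fingerprint-bit substructure
    interpretation. Ships a synthetic molecule-library generator with
    planted structure-activity signal so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
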