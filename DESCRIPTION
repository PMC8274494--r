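Package: erqsar
Title: Dual-Target QSAR Classification for Estrogen Receptor Subtype Selectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A classification structure-activity relationship (CSAR) workflow for
    building and deploying dual-target bioactivity classifiers against the
    estrogen receptor subtypes ERalpha and ERbeta. Takes ChEMBL-style IC50
    activity tables and SMILES through structure standardization, pIC50
    conversion and active/inactive labelling, dictionary-based substructure
    fingerprints (presence and count modes), near-constant feature filtering,
    Kennard-Stone rational train/test splitting, tuned random-forest models
    with accuracy/sensitivity/specificity/Matthews-correlation evaluation and
    mean-decrease-Gini feature ranking, a PCA bounding-box applicability
    domain, and a batch predictor that reports per-subtype activity calls with
    a selectivity classification. Includes a synthetic benchmark generator
    with planted, recoverable substructure signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    randomForest,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
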