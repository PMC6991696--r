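Package: exopanel
Title: Circulating Exosomal lncRNA Biomarker Panel Discovery and Risk-Score
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multiphase case-control analysis pipeline for circulating
    exosomal long non-coding RNA (lncRNA) biomarker panels measured by qPCR.
    Implements spike-in-normalized comparative 2^-ddCt relative
    quantification with explicit handling of Ct-censored nondetects,
    filtered differential screening across ordered clinical groups with
    Venn-style candidate intersection, a binary-coded weighted risk-score
    classifier with control-derived reference-interval thresholds and a
    Youden-style cut-off, and frozen-model evaluation (ROC/AUC, sensitivity,
    specificity, PPV, NPV, double-blind accuracy) on training, validation
    and blind splits. A seeded synthetic cohort generator emulates the
    four-group hepatocellular carcinoma study design so every stage is
    testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
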