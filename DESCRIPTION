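Package: cpqsar
Title: Counter-Propagation Neural Network QSAR Models with Consensus
    Predictions and Applicability Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ligand-based QSAR modelling of membrane-transporter
    activity. Implements descriptor preprocessing (autoscaling, zero-variance
    and intercorrelation filters, Kohonen-map similarity reduction),
    counter-propagation artificial neural networks and multiple linear
    regression for classification and regression of inhibition constants,
    genetic-algorithm descriptor selection with cross-validated fitness,
    leverage- and Euclidean-distance-based applicability domains,
    multi-model consensus calls with agreement typing, and an external
    validation suite (sensitivity, specificity, MCC, ROC/AUC, Q2F3, Lin's
    concordance, rm2). A synthetic-data generator reproduces the statistical
    structure of a transporter inhibition dataset so the whole pipeline can
    be exercised end to end without commercial descriptor software.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
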