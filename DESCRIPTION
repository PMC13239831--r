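Package: mfcpnet
Title: Multi-Pattern Functional Connectivity Networks and Graph
    Convolutional Classification for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-subject brain functional connectivity networks
    from ROI time series under three complementary connection patterns
    (Pearson correlation, L1-penalised sparse representation, and pairwise
    Granger causality), classifies subjects with a multi-branch first-order
    spectral graph convolutional network with mean/max readout and a fused
    fully connected head, and attributes predictions to regions with
    node-level Grad-CAM. Includes a stationary VAR(1) cohort simulator for
    two-group studies, stratified split / repeated-run / cross-validation
    drivers, pattern-subset ablation, and lambda and threshold sensitivity
    sweeps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    lmtest,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
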