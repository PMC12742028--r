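Package: megstates
Title: Single-Trial Decoding of Meditative Self-Boundary States from
    Parcellated MEG Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses parcellated magnetoencephalography
    (MEG) recordings of alternating meditative states (self-boundary
    dissolution, self-boundary maintenance, rest). Provides a synthetic
    session generator with planted spectral and complexity effects,
    aperiodic-corrected band-power and normalized Lempel-Ziv (LZ76)
    complexity features, leakage-aware within- and across-participant
    classification (L1 logistic regression, RBF support vector machine,
    random forest, Gaussian naive Bayes) with SMOTE rebalancing and
    grid-search cross-validation, and the accompanying inferential stack
    (exact binomial tests, Fisher combination, Benjamini-Hochberg FDR,
    Spearman correlations with default Bayes factors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    e1071,
    ranger,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    arrow,
    optparse,
    knitr
Config/testthat/edition: 3
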