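Package: stiffsense
Title: Tissue Stiffness Classification from Ultrasonic Aspirator Signal Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for machine-learning-based
    differentiation of soft tissue stiffness classes from multichannel
    electrical signals recorded by an ultrasonic surgical aspirator. Provides
    a synthetic multichannel recording generator with idle/contact phase
    structure and injectable periodic irrigation noise, zero-phase Butterworth
    low-pass and notch (band-stop) preprocessing filters realized as cascaded
    biquad sections, three classifiers (a random forest baseline, an
    autoencoder-regularized fully connected network trained with a combined
    cross-entropy plus reconstruction loss, and a 1D residual convolutional
    network over sliding windows), recording-disjoint stratified k-fold
    cross-validation, and a classifier-by-filter experiment grid reporting
    F1, accuracy, precision, recall and AUROC.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    signal,
    pROC,
    optparse
Config/testthat/edition: 3
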