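Package: cswv
Title: Simulation and Classification of Cyclic Square-Wave Voltammograms
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Chemometric identification of bioactive and hazardous compounds
    from cyclic square-wave voltammetry (CSWV). Simulates labeled seawater and
    generic scan libraries with class-specific stripping and reduction peaks on
    a reconstructed index-potential grid, and trains and compares seven
    classifiers of the concatenated cathodic+anodic current traces: PCA-SVM,
    LDA, 1-NN dynamic time warping with a Sakoe-Chiba band, and four neural
    time-series models (LSTM with dimension shuffle, fully convolutional
    network, LSTM-FCN and attention LSTM-FCN) trained with Adam under a
    plateau learning-rate schedule and inverse-frequency class weighting.
    Provides repeated stratified train/test evaluation (macro-F1, per-class
    and micro/macro ROC-AUC), cell-number and batch-size refinement sweeps,
    class-activation maps for the convolutional models, and a CAM-guided
    trace-truncation experiment.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    MASS,
    e1071,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
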