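Package: ppgbioid
Title: Biometric Identification from Photoplethysmogram Scalograms with a
    Hybrid CVT-ConvMixer Classifier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for person identification from single-channel
    photoplethysmogram (PPG) signals. Provides a synthetic PPG cohort
    generator (two-Gaussian pulse model with heart-rate variability, baseline
    wander, ambient tones and motion-artifact bursts), signal preprocessing
    (zero-phase bandpass filtering, baseline removal, PCA-based artifact
    suppression, normalization, cubic resampling, overlapping segmentation and
    SNR-based quality screening), Morlet continuous-wavelet-transform
    scalogram imaging, and a natively implemented hybrid convolutional vision
    transformer / ConvMixer neural classifier with attentional feature fusion,
    residual and channel-attention enhancement, trained by reverse-mode
    automatic differentiation with Adam or SGD-momentum. Includes one-vs-rest
    evaluation metrics, ROC AUC, subject-grouped stratified cross-validation
    and a rotating cross-source validation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    png,
    EBImage,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
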