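Package: dotriage
Title: Two-Stage Breast Lesion Classification with Ultrasound-Guided
    Diffuse Optical Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for breast lesion diagnosis from
    ultrasound-guided frequency-domain diffuse optical tomography (DOT).
    Simulates Born-consistent frequency-domain reflectance for spherical
    absorbers in a semi-infinite diffusive medium, forms bivariate
    perturbation histograms, reconstructs total-hemoglobin maps by
    Tikhonov-regularized conjugate-gradient Born inversion on a
    US-guided dual mesh, trains three convolutional feature-extraction
    branches (ultrasound image, DOT histogram, DOT image) with a fusion
    classifier, and evaluates a two-stage triage strategy (cheap benign
    screening first, selective reconstruction and fusion diagnosis
    second) with balanced bootstrap resampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
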