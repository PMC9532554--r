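Package: progreg
Title: Progressive Self-Calibrating Deformable 3D Image Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised deformable registration of 3D grayscale volumes by a
    progressive, self-calibrating strategy: a single shared-weight convolutional
    network is applied repeatedly to predict per-pass displacement vector
    fields, which are algebraically aggregated into one total field so that the
    moving image is interpolated exactly once. A two-scale coarse-to-fine
    cascade upsamples the low-resolution aggregate as the initial value of the
    full-resolution chain. Includes local normalized cross-correlation and
    smoothness losses, Adam training on CPU, Dice and edge-sharpness
    evaluation, NIfTI input/output, a labeled-phantom generator with
    controllable deformation severity, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
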