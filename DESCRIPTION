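Package: pupilsize
Title: Pupil Size Estimation from Eye Images with Dilated Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating pupil size (major and minor ellipse axis
    lengths, in pixels) from grayscale eye images. Provides a synthetic
    eye-image renderer with exact ellipse ground truth, direct least-squares
    ellipse fitting for ground-truth labeling, structural-similarity (SSIM)
    based frame sampling for video-derived datasets, geometric augmentation
    with consistent label transformation, a family of small dilated-convolution
    regression networks trained with a staged schedule, pooled percent-error
    evaluation of axis lengths and ellipse area, and Grad-CAM visualization
    of the trained regressor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
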