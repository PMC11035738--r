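Package: facelesion
Title: Feature Lesioning and Grad-CAM Analysis of Face Identity
    Recognition in Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for probing which facial features a convolutional
    identity classifier relies on. Provides a parametric synthetic face
    generator with ground-truth landmarks, exact-area feature masking and
    graded region-restricted Gaussian blur lesions, a small trainable
    convolutional classifier with Grad-CAM heatmaps, and the experiment
    statistics used in feature-lesioning studies: importance ranking,
    blur-level curves, random-mask controls, pairwise super-additivity,
    error-set overlap, emphasis-redirection tables, and paired bootstrap
    significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
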