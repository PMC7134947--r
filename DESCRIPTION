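Package: plotspectra
Title: Plot-Level Hyperspectral Phenotyping of Photosynthetic Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating photosynthetic capacity and
    pigment traits from proximal push-broom hyperspectral imagery of crop
    plots. Converts raw digital-number hypercubes to radiance, segments plot
    scenes into material classes by K-means clustering, converts sunlit-leaf
    radiance to reflectance against an in-scene white reference panel,
    smooths and masks noisy and water-absorption bands, joins two-camera
    spectra, and fits partial least squares regression (PLSR) trait models
    with PRESS-based latent-variable selection, resampling validation, and
    variable-importance-in-projection diagnostics. Also provides the
    leaf-level physiology fitters that produce the ground-truth traits:
    Farquhar-von Caemmerer-Berry A/Ci curve fitting with a
    temperature-constrained mesophyll conductance, and non-rectangular
    hyperbola light-response fitting. A synthetic scene and response-curve
    generator with known ground truth makes every stage testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    signal,
    withr
Config/testthat/edition: 3
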