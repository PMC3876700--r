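Package: retivess
Title: Multiresolution Hessian-Based Retinal Vessel Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments the blood vessel tree in color fundus photographs using
    single-scale Frangi vesselness applied across a halving Gaussian resolution
    hierarchy. Includes green-channel preprocessing (histogram stretching,
    bilateral denoising), specular-reflex correction on coarse pyramid levels,
    per-level hysteresis binarization with percentile-derived thresholds,
    morphological postprocessing (OR-fusion, gradient-guided thinning, closing,
    object-size cleanup), a reference multiscale Frangi backend for comparison,
    pixelwise evaluation against gold-standard masks, and a seeded synthetic
    fundus-phantom generator with ground truth for self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
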