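Package: SphereMap
Title: Spherical Surface Fitting, Mercator Unwrapping and Spot Counting
    for Light-Sheet Embryo Volumes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing whole-embryo light-sheet fluorescence
    volumes of approximately spherical embryos. Estimates the embryo
    surface by binning, adaptive local-mean binarization, boundary
    point-cloud extraction and algebraic linear least-squares sphere
    fitting; unwraps concentric spherical shells onto conformal 2D
    Mercator map images (multi-layer stacks and cross-layer maximum
    projections); and counts reporter-positive cells by baseline
    subtraction and 3D local-maximum spot detection restricted to
    physical regions of interest over developmental time courses. A
    synthetic-embryo simulator with exact ground truth (cells on a
    spherical shell, yolk autofluorescence, Poisson and Gaussian camera
    noise, anisotropic voxels) supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
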