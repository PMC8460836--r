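Package: lumenmorph
Title: Lumen Morphometry and a Two-Dimensional Vertex Model of Epithelial
    Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the three-dimensional and cross-sectional geometry of
    epithelial lumens from binary segmentation masks (Fourier contour smoothing
    with BIC order selection, mean curvature from orthogonal cross-sections,
    sphericity, solidity, isoperimetric quotient, normalized lumen radius) and
    simulates lumen growth with a dimensionless two-dimensional vertex-based
    mechanical model of a spheroid (luminal pressure, area elasticity, and
    apical/basal/lateral length springs, minimized by stochastic gradient
    descent with division of the highest-energy cell). Includes the matching
    statistical machinery (two-sample two-dimensional Kolmogorov-Smirnov test,
    exact-matching weights, weighted Welch's t-test) and synthetic phantom
    generators with analytic ground truth so the whole pipeline is testable
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
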