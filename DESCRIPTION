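Package: mechanophen
Title: Mechanical Phenotyping of Cells and Clusters from Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Image-analysis and cell-mechanics toolkit for distinguishing
    mechanical phenotypes of tumor cell populations. Implements traction force
    microscopy (particle image velocimetry plus regularized Fourier-transform
    traction cytometry on an elastic half-space), traction dipole anisotropy,
    cell shape and deformability metrics with deformability-cytometry gating,
    active-wetting contact angles from spherical-cap geometry, object
    segmentation and intensity ratios (including nuclear-to-cytoplasmic YAP),
    centroid tracking with accumulated-distance velocities, and single-cell
    stemness-signature scoring with percentile classification. A bundled
    synthetic-microscopy generator provides every input with known ground
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
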