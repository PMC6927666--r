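Package: plamech
Title: Proximity-Ligation-Assay Punctum Quantification and AFM
    Force-Spectroscopy Analysis for Endothelial Mechanophenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: High-content quantification of proximity ligation assay (PLA)
    micrographs -- nucleus segmentation by Gaussian smoothing, Huang
    auto-thresholding and binary watershed; punctum detection by rolling-ball
    background subtraction, difference-of-Gaussians enhancement, isodata
    thresholding and median filtering; partition of puncta into nuclear and
    cytosolic compartments -- together with atomic force microscopy (AFM)
    force-spectroscopy analysis: deflection-sensitivity calibration, baseline
    correction, contact-point detection, force-indentation conversion,
    linearized spherical Hertz and conical Sneddon elasticity fits, and
    quantitative-imaging (QI) stiffness/height map reconstruction. Seeded
    synthetic-data generators provide ground-truthed images and force curves
    so every pipeline stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
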