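Package: ppixquant
Title: Quantitative PpIX Fluorescence Imaging with Dye-in-Polymer Reference Standards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification pipeline for protoporphyrin IX (PpIX)
    fluorescence imaging under an operating microscope's blue excitation light.
    Models the illumination field (bell-shaped, vertically skewed beam; power-law
    distance response), renders synthetic scenes of photostable dye-in-polymer
    reference standards together with photobleaching tumor and brain tissue
    through internal-CCD and external filtered camera models, extracts circular
    ROI intensity time series, performs ratiometric normalization against a
    reference standard, fits logarithmic photobleaching kinetics with pseudo-R
    squared and two-point half-life, and computes multi-rater ordinal agreement
    statistics (pairwise agreement, fixed-marginal and free-marginal kappa).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
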