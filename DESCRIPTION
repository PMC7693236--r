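Package: fragmon
Title: Inter-Fraction Treatment Monitoring from Charged-Fragment Emission Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects inter-fractional morphological changes in scanned
    carbon-ion therapy from the emission maps of secondary charged fragments
    measured by an external tracker. Fragment tracks are backprojected to
    their points of closest approach (PCA) with the planned pencil-beam axes,
    aggregated into super pencil beams sharing an end-range cell, reduced to
    dead-time-corrected 1D emission profiles, and compared between treatment
    sessions with chi-square and Kolmogorov-Smirnov tests including a
    detector-positioning systematic and leading-edge masking. 2D range maps
    localize flagged changes and read out distal-edge shifts. A seeded
    synthetic delivery and detector simulator provides plans, phantoms and
    per-fraction track lists with ground truth for calibration and
    sensitivity studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    arrow,
    optparse
Config/testthat/edition: 3
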