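Package: senCPM
Title: Cellular Potts Simulation and Trajectory Analysis of Mixed
    Normal/Senescent Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lattice-based Cellular Potts Model (CPM) of a binary mixture
    of motile (normal) and enlarged, non-motile (senescent) breast-cancer
    cells, together with the trajectory statistics used to calibrate it:
    polar decomposition of orbits around a host cell, chirality
    rectification, angular and tangential speeds, contact-episode
    detection with gamma fits of residence times, contact-conditioned
    directional persistence, and a two-parameter phase scan whose
    level-curve intersection estimates the normal-senescent interfacial
    adhesion energy. Includes synthetic-trajectory generators emulating
    the experimental orbit statistics so the analysis pipeline is
    testable independently of the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    minpack.lm,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
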