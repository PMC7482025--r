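Package: adhesim
Title: Hybrid Cellular Potts-Finite Element Simulation of Focal Adhesion
    Mechanosensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single cells on elastic substrates with a hybrid
    cellular Potts model (CPM) coupled to a plane-stress finite-element
    description of the substrate and per-site ordinary differential
    equation models of focal adhesion (FA) turnover. Focal adhesions are
    clusters of integrin catch-slip bonds fed from a finite membrane pool;
    cell traction forces build up at a stiffness-dependent rate and load
    the clusters, so that adhesions stabilize on stiff substrates and
    disassemble on soft ones. From this single assumption set the model
    produces stiffness-dependent cell spreading, biphasic cell elongation
    under matrix-stress feedback, and durotaxis on stiffness gradients.
    Includes substrate stiffness field generators (homogeneous, noisy,
    sinusoidal, linear gradient), morphometric analysis (area and
    eccentricity time courses, spreading-kinetics fits, adhesion size
    statistics, trajectory velocimetry), experiment presets, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
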