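Package: pbexciton
Title: Compartmental Exciton-Transfer Simulation and Single-Molecule
    Photon-Stream Analysis for OCP-Quenched Phycobilisomes
Version: 0.1.0
Authors@R:
    person("pbexciton", "developers", email = "pbexciton@example.org",
           role = c("aut", "cre"))
Description: Tools to model non-photochemical quenching of the cyanobacterial
    phycobilisome antenna by the Orange Carotenoid Protein (OCP). Provides a
    compartmental exciton-transfer network for the truncated CB-PB
    phycobilisome with attachable OCP quencher sinks, exact observables by
    absorbing Markov-chain linear algebra, photon-by-photon Monte-Carlo
    simulation (fixed-step and continuous-time samplers), a synthetic-data
    generator emulating ABEL-trap multiparameter photon streams (two
    polarization channels, TCSPC delays, 50 Hz spectral camera frames), and
    the single-molecule analysis pipeline: per-group brightness, fluorescence
    polarization, IRF-convolved maximum-likelihood lifetime fitting with
    Fisher errors, spectral calibration and center of mass, photophysical
    state classification with 95 percent confidence ellipses, level
    segmentation, population kinetics, and a constrained hexamer-mixture
    brightness fit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
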