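Package: amparkinetics
Title: Simulation and Kinetic Analysis of AMPA-Receptor Patch-Clamp and
    Synaptic Currents
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantitative analysis of ligand-gated ion-channel currents:
    multi-exponential decay fitting of deactivation, desensitization and
    EPSC decays; non-stationary fluctuation analysis inverting the
    variance-mean parabola to unitary current, channel number, open
    probability and single-channel conductance; current-voltage curves and
    rectification indices; miniature and evoked synaptic-current analysis
    (event detection, averaged-event kinetics, paired-pulse ratio, charge
    transfer); and a stochastic Markov channel-gating and synaptic-recording
    simulator with known ground truth so that every analysis stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    minpack.lm,
    pracma,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
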