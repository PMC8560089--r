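Package: undulator
Title: Threshold-Switch Relaxation Oscillator Analysis of C. elegans Undulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for a proprioceptive threshold-switch
    relaxation oscillator model of C. elegans locomotor rhythm generation in the
    head segment. Provides the five-parameter oscillator (bending relaxation,
    muscle switching, moment amplitude, proprioceptive velocity weight and
    threshold), transient optogenetic muscle-inhibition simulations with a
    bell-shaped suppression envelope, phase-response-curve construction for the
    model and for curvature time series, phase-portrait estimators of the
    bending and muscle time constants, a two-round parameter fitting procedure,
    viscosity-dependent gait adaptation, alternative oscillator models
    (van der Pol, Rayleigh, Stuart-Landau) under the same perturbation
    interface, and a synthetic-data generator emulating the perturbation-trial
    structure of behavioral experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
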