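Package: oculopd
Title: Saccade and Pupillometry Analysis for Early Parkinson's Disease Screening
Version: 0.1.0
Authors@R:
    person("Aerospace", "Oculomotor Lab", email = "oculopd@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of virtual-reality pro-saccade and
    anti-saccade eye-tracking recordings for early-stage Parkinson's disease
    research. Provides a stimulus-protocol model, a synthetic cohort generator
    with group-dependent saccade dynamics and band-structured pupil
    oscillations, blink/artifact preprocessing, velocity-threshold saccade
    detection with trial scoring, Fourier amplitude spectra of pupil-diameter
    traces on a 0.1 Hz grid, normality-gated two-group statistics with
    band-wise significance counting, and a random-forest diagnostic
    classifier evaluated over feature-set configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
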