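Package: nmcoupling
Title: Descending Motor Pathway Simulation and n:m Spectral Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation of direct (mono-synaptic) and
    indirect (multi-synaptic) descending motor pathways, built from layers of
    single-compartment Hodgkin-Huxley interneurons feeding a pool of
    two-compartment motoneurons with persistent inward currents.  Provides a
    beta-band supraspinal drive generator, calibration routines that pin EPSP
    amplitudes, interspike-interval variability and firing-rate ranges to
    physiological targets, and a generalized n:m coherence (NMC) analysis of
    the coupling between the supraspinal input and cumulative spike train
    outputs, including surrogate-based significance with family-wise error
    control and the cross-over-iso coupling index (COI).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
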