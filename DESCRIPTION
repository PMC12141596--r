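Package: kcnqres
Title: Conductance-Based Modelling of KCNQ Channel Gating and Membrane Resonance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hodgkin-Huxley-style models of KCNQ (Kv7) potassium channels, with and
    without a rapid-inactivation gate, embedded in a single-compartment cell.
    Simulates voltage-clamp and current-clamp protocols (voltage-step families,
    sinusoidal clamp, ZAP chirp currents), computes impedance amplitude profiles
    and resonance metrics (resonant frequency and strength), detects membrane
    potential oscillations by Welch power spectra, quantifies opposing conductance
    transients at voltage-step transitions, fits Boltzmann activation curves and
    single-exponential kinetics, and provides an analytic parallel RLC circuit with
    a leaky inductor as a reference for inductor-like channel gating. A synthetic
    whole-cell recording generator (paired control/blocker sweeps, parameter-level
    mutants) makes every analysis stage testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
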