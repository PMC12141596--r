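# Shared fixtures: the standard HEK-like model cell in its three
# configurations, plus small helpers used across test files.

cell_passive <- function() cell_model()

cell_kcnq <- function() cell_model(channels = list(kcnq_model()))

cell_kcnqi <- function() cell_model(channels = list(kcnq_inactivation_model()))

# analytic impedance magnitude of the passive RC cell, MOhm
rc_impedance_mag <- function(cell, f_Hz) {
  R <- input_resistance(cell)              # MOhm
  C <- total_capacitance(cell)             # pF
  R / sqrt(1 + (2 * pi * f_Hz * R * 1e6 * C * 1e-12)^2)
}

# random gating parameter set drawn inside a physiological envelope
random_gating <- function() {
  gating_params(theta = stats::runif(1, -80, -20),
                k = stats::runif(1, 5, 25),
                tau0 = stats::runif(1, 2, 20),
                tau1 = stats::runif(1, 30, 200),
                phi = stats::runif(1, -80, -20),
                sigma0 = stats::runif(1, 15, 40),
                sigma1 = -stats::runif(1, 15, 40),
                floor = 0, exponent = sample(1:4, 1))
}
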