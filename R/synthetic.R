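#' Specification for a synthetic paired whole-cell recording
#'
#' Describes how to emulate a control/blocker pair of voltage-clamp sweeps:
#' the model channel current plus a linear leak plus i.i.d. Gaussian noise,
#' with the blocker sweep carrying the channel current scaled by
#' `1 - block_fraction` and independent noise.
#'
#' @param cell A `cell_model` whose channels generate the current.
#' @param command Voltage-command `ephys_trace` of the protocol.
#' @param noise_sd_pA Gaussian noise SD on the recorded current (pA, >= 0).
#' @param leak_g_nS Linear leak conductance (nS).
#' @param leak_e_mV Leak reversal (mV).
#' @param block_fraction Fraction of the channel conductance removed by the
#'   blocker, in [0, 1].
#' @param seed Integer RNG seed; the generator is a pure function of
#'   (spec, seed).
#' @return A `recording_spec` object.
#' @export
recording_spec <- function(cell, command, noise_sd_pA = 2, leak_g_nS = 1,
                           leak_e_mV = -40, block_fraction = 1, seed = 1L) {
  stopifnot(inherits(cell, "cell_model"),
            inherits(command, "ephys_trace"), command$kind == "voltage",
            noise_sd_pA >= 0, block_fraction >= 0, block_fraction <= 1)
  structure(list(cell = cell, command = command, noise_sd_pA = noise_sd_pA,
                 leak_g_nS = leak_g_nS, leak_e_mV = leak_e_mV,
                 block_fraction = block_fraction, seed = as.integer(seed)),
            class = "recording_spec")
}

#' Generate a paired control/blocker synthetic recording
#'
#' `control = I_channel + I_leak + noise`;
#' `blocked = (1 - block_fraction) * I_channel + I_leak + noise'` with
#' independent noise draws.  Deterministic given the spec's seed.
#'
#' @param spec A `recording_spec`.
#' @return List with current traces `control` and `blocked`, plus
#'   `channel_current` (the noise-free model current) and the underlying
#'   `sim` result.
#' @export
make_paired_recordings <- function(spec) {
  stopifnot(inherits(spec, "recording_spec"))
  sim <- run_voltage_clamp(spec$cell, spec$command)
  i_chan <- sim$response$values
  i_leak <- spec$leak_g_nS * (spec$command$values - spec$leak_e_mV)
  n <- length(i_chan)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  noise1 <- stats::rnorm(n, 0, spec$noise_sd_pA)
  noise2 <- stats::rnorm(n, 0, spec$noise_sd_pA)
  dt <- spec$command$dt
  t0 <- spec$command$t0
  list(control = ephys_trace(i_chan + i_leak + noise1, dt, "current", t0),
       blocked = ephys_trace((1 - spec$block_fraction) * i_chan + i_leak +
                               noise2, dt, "current", t0),
       channel_current = sim$response,
       sim = sim)
}

#' Parameter-level mutant channel variant
#'
#' Emulates a mutant as a shift of the activation midpoint (`dvhalf_mV`,
#' negative = hyperpolarizing / gain-of-function-like) and a scaling of the
#' activation time constants (`tau_scale < 1` = faster kinetics,
#' loss-of-function-like deactivation).
#'
#' @param base A `channel_model`.
#' @param dvhalf_mV Shift added to the activation midpoint (mV).
#' @param tau_scale Positive factor applied to `tau0` and `tau1`.
#' @return A `channel_model`.
#' @export
make_mutant_params <- function(base, dvhalf_mV = 0, tau_scale = 1) {
  stopifnot(inherits(base, "channel_model"), tau_scale > 0)
  a <- base$activation
  act <- gating_params(theta = a$theta + dvhalf_mV, k = a$k,
                       tau0 = a$tau0 * tau_scale, tau1 = a$tau1 * tau_scale,
                       phi = a$phi + dvhalf_mV, sigma0 = a$sigma0,
                       sigma1 = a$sigma1, floor = a$floor,
                       exponent = a$exponent)
  channel_model(base$gmax_density, act, base$inactivation,
                label = sprintf("%s_mut(%+g mV, x%g)", base$label, dvhalf_mV,
                                tau_scale))
}

#' Remove the rapid-inactivation gate from a channel model
#'
#' Emulates pharmacological suppression of rapid inactivation by clamping
#' the h gate to 1 (i.e., removing it), leaving activation untouched.
#'
#' @param model A `channel_model` with an inactivation gate.
#' @return A `channel_model` without inactivation.
#' @export
make_ica_variant <- function(model) {
  stopifnot(inherits(model, "channel_model"))
  if (is.null(model$inactivation))
    stop("model has no inactivation gate to remove")
  channel_model(model$gmax_density, model$activation, NULL,
                label = paste0(model$label, "_noinact"))
}
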