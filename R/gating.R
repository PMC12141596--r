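#' Gating-variable parameters
#'
#' Parameters of one Hodgkin-Huxley gating variable with a Boltzmann steady
#' state and a double-sigmoid voltage-dependent time constant:
#' \deqn{x_\infty(V) = floor + (1 - floor) / (1 + \exp[(\theta - V)/k])}
#' \deqn{\tau_x(V) = \tau_0 + (\tau_1 - \tau_0) /
#'       (\exp[(\phi - V)/\sigma_0] + \exp[(\phi - V)/\sigma_1])}
#'
#' @param theta Half-activation voltage of the steady state (mV).
#' @param k Slope factor (mV, signed; negative for inactivation gates).
#' @param tau0,tau1 Limiting time constants (ms, > 0).
#' @param phi Center of the time-constant curve (mV).
#' @param sigma0,sigma1 Slope factors of the time-constant curve (mV, signed).
#' @param floor Lower bound of the steady state (fraction in [0, 1); 0 for
#'   activation gates, `h_min` for inactivation gates).
#' @param exponent Integer power the gate enters the conductance with
#'   (4 for the activation gate, 1 for inactivation).
#' @return A `gating_params` object.
#' @export
gating_params <- function(theta, k, tau0, tau1, phi, sigma0, sigma1,
                          floor = 0, exponent = 1L) {
  stopifnot(is.finite(theta), is.finite(k), k != 0,
            is.finite(phi), is.finite(sigma0), is.finite(sigma1),
            sigma0 != 0, sigma1 != 0)
  if (!is.finite(tau0) || !is.finite(tau1) || tau0 <= 0 || tau1 <= 0)
    stop("tau0 and tau1 must be positive")
  if (floor < 0 || floor >= 1) stop("floor must lie in [0, 1)")
  exponent <- as.integer(exponent)
  if (exponent < 1L) stop("exponent must be a positive integer")
  p <- list(theta = theta, k = k, tau0 = tau0, tau1 = tau1, phi = phi,
            sigma0 = sigma0, sigma1 = sigma1, floor = floor,
            exponent = exponent)
  class(p) <- "gating_params"
  # the double-sigmoid can dip below tau0 when sigma0 and sigma1 share a
  # sign; reject parameter sets whose tau is not strictly positive
  vgrid <- seq(-150, 100, by = 0.5)
  if (any(gate_time_constant(vgrid, p) <= 0))
    stop("time-constant curve is not strictly positive for these parameters")
  p
}

#' @export
print.gating_params <- function(x, ...) {
  cat(sprintf(
    "<gating_params> theta=%g mV k=%g mV tau0=%g tau1=%g ms phi=%g mV\n",
    x$theta, x$k, x$tau0, x$tau1, x$phi))
  cat(sprintf("  sigma0=%g sigma1=%g mV floor=%g exponent=%d\n",
              x$sigma0, x$sigma1, x$floor, x$exponent))
  invisible(x)
}

#' Steady-state value of a gate
#'
#' @param V Membrane potential (mV); vectorized.
#' @param p A `gating_params` object.
#' @return Steady-state open fraction in `[floor, 1]`.
#' @export
gate_steady_state <- function(V, p) {
  stopifnot(inherits(p, "gating_params"))
  if (any(!is.finite(V))) stop("V must be finite")
  p$floor + (1 - p$floor) / (1 + exp((p$theta - V) / p$k))
}

#' Voltage-dependent time constant of a gate
#'
#' @inheritParams gate_steady_state
#' @return Time constant in ms (strictly positive).
#' @export
gate_time_constant <- function(V, p) {
  if (any(!is.finite(V))) stop("V must be finite")
  p$tau0 + (p$tau1 - p$tau0) /
    (exp((p$phi - V) / p$sigma0) + exp((p$phi - V) / p$sigma1))
}

#' Advance a gate over one step at frozen voltage
#'
#' Exact solution of `dx/dt = (x_inf(V) - x)/tau(V)` over `dt` with `V` held
#' constant: `x_inf + (x - x_inf) * exp(-dt/tau)`.
#'
#' @param state Current gate value.
#' @param V Membrane potential (mV) during the step.
#' @param dt Step length (ms, >= 0).
#' @param p A `gating_params` object.
#' @return Updated gate value; stays within `[floor, 1]` if `state` starts
#'   within bounds.
#' @export
gate_update <- function(state, V, dt, p) {
  stopifnot(inherits(p, "gating_params"))
  if (any(dt < 0)) stop("dt must be non-negative")
  xi <- gate_steady_state(V, p)
  xi + (state - xi) * exp(-dt / gate_time_constant(V, p))
}

#' Channel model
#'
#' A maximal conductance density together with an activation gate and an
#' optional rapid-inactivation gate.  The conductance is
#' `gmax * m^exponent_m * h^exponent_h` (h absent means h = 1).
#'
#' @param gmax_density Maximal conductance density (S/cm^2, >= 0).
#' @param activation `gating_params` for the activation gate m.
#' @param inactivation Optional `gating_params` for the inactivation gate h.
#' @param label Character label for printing.
#' @return A `channel_model` object.
#' @export
channel_model <- function(gmax_density, activation, inactivation = NULL,
                          label = "channel") {
  stopifnot(inherits(activation, "gating_params"), gmax_density >= 0)
  if (!is.null(inactivation)) stopifnot(inherits(inactivation, "gating_params"))
  structure(list(gmax_density = gmax_density, activation = activation,
                 inactivation = inactivation, label = label),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf("<channel_model> '%s': gmax = %g S/cm^2, m^%d%s\n",
              x$label, x$gmax_density, x$activation$exponent,
              if (is.null(x$inactivation)) ""
              else sprintf(" * h^%d (floor %g)", x$inactivation$exponent,
                           x$inactivation$floor)))
  invisible(x)
}

#' Channel conductance from gate state
#'
#' @param m Activation gate value(s).
#' @param model A `channel_model`.
#' @param area_cm2 Membrane area in cm^2 (> 0).
#' @param h Inactivation gate value(s); defaults to 1.
#' @return Conductance in nS.
#' @export
channel_conductance <- function(m, model, area_cm2, h = 1) {
  stopifnot(inherits(model, "channel_model"))
  if (area_cm2 <= 0) stop("area must be positive")
  hexp <- if (is.null(model$inactivation)) 1L else model$inactivation$exponent
  g_S <- model$gmax_density * m^model$activation$exponent * h^hexp * area_cm2
  g_S * 1e9
}

#' Ohmic channel current
#'
#' `I = g * (V - E_K)`; outward current is positive.
#'
#' @param g Conductance in nS (>= 0).
#' @param V Membrane potential (mV).
#' @param E_K Potassium reversal potential (mV).
#' @return Current in pA.
#' @export
channel_current <- function(g, V, E_K) {
  if (any(g < 0)) stop("conductance must be non-negative")
  g * (V - E_K)
}

#' Steady-state channel conductance density at a voltage
#'
#' @param V Membrane potential (mV); vectorized.
#' @param model A `channel_model`.
#' @return Conductance density in S/cm^2.
#' @export
steady_conductance_density <- function(V, model) {
  m <- gate_steady_state(V, model$activation)
  h <- if (is.null(model$inactivation)) 1
       else gate_steady_state(V, model$inactivation)
  hexp <- if (is.null(model$inactivation)) 1L else model$inactivation$exponent
  model$gmax_density * m^model$activation$exponent * h^hexp
}

# internal: flatten a channel_model into the list the C++ integrators take
channel_cpp_spec <- function(model, area_cm2) {
  g <- function(p) list(theta = p$theta, k = p$k, tau0 = p$tau0,
                        tau1 = p$tau1, phi = p$phi, sigma0 = p$sigma0,
                        sigma1 = p$sigma1, floor = p$floor,
                        exponent = p$exponent)
  list(gmax_nS = model$gmax_density * area_cm2 * 1e9,
       m = g(model$activation),
       h = if (is.null(model$inactivation)) NULL else g(model$inactivation))
}

#' Load channel models from a YAML parameter file
#'
#' The file holds one section per channel; each section has `gmax_S_cm2` and
#' gate sub-sections `m` and optionally `h` with keys `theta_mV`, `k_mV`,
#' `tau0_ms`, `tau1_ms`, `phi_mV`, `sigma0_mV`, `sigma1_mV`, `floor`,
#' `exponent`.  Units are encoded in the key names.
#'
#' @param path YAML file path.
#' @return Named list of `channel_model` objects.
#' @export
read_channel_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  parse_gate <- function(g) {
    gating_params(theta = g$theta_mV, k = g$k_mV, tau0 = g$tau0_ms,
                  tau1 = g$tau1_ms, phi = g$phi_mV, sigma0 = g$sigma0_mV,
                  sigma1 = g$sigma1_mV,
                  floor = if (is.null(g$floor)) 0 else g$floor,
                  exponent = if (is.null(g$exponent)) 1L else g$exponent)
  }
  out <- lapply(names(cfg), function(nm) {
    ch <- cfg[[nm]]
    channel_model(gmax_density = ch$gmax_S_cm2,
                  activation = parse_gate(ch$m),
                  inactivation = if (is.null(ch$h)) NULL else parse_gate(ch$h),
                  label = nm)
  })
  names(out) <- names(cfg)
  out
}

#' Write channel models to a YAML parameter file
#'
#' Inverse of [read_channel_params()]; round-trips losslessly.
#'
#' @param models Named list of `channel_model` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_channel_params <- function(models, path) {
  gate_out <- function(p) list(
    theta_mV = p$theta, k_mV = p$k, tau0_ms = p$tau0, tau1_ms = p$tau1,
    phi_mV = p$phi, sigma0_mV = p$sigma0, sigma1_mV = p$sigma1,
    floor = p$floor, exponent = p$exponent)
  cfg <- lapply(models, function(m) {
    out <- list(gmax_S_cm2 = m$gmax_density, m = gate_out(m$activation))
    if (!is.null(m$inactivation)) out$h <- gate_out(m$inactivation)
    out
  })
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

# path of the packaged default parameter file
default_params_path <- function() {
  system.file("extdata", "kcnq_params_synthetic.yaml", package = "kcnqres",
              mustWork = TRUE)
}

#' Default KCNQ channel model
#'
#' Activation-only KCNQ (Kv7) model, `g = gmax * m^4`, loaded from the
#' packaged parameter file.  The packaged kinetic values are a synthetic
#' reconstruction in the lineage of published globus-pallidus KCNQ kinetics
#' (see the parameter file and the methods vignette).
#'
#' @return A `channel_model`.
#' @export
kcnq_model <- function() {
  read_channel_params(default_params_path())$kcnq
}

#' Default KCNQ model with rapid inactivation
#'
#' The same activation gate as [kcnq_model()] with a rapid inactivation gate
#' h (with a non-zero floor `h_min`): `g = gmax * m^4 * h`.  The h-gate
#' parameters are a synthetic, ERG-like reconstruction (see the methods
#' vignette).
#'
#' @return A `channel_model`.
#' @export
kcnq_inactivation_model <- function() {
  read_channel_params(default_params_path())$kcnq_inactivation
}
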