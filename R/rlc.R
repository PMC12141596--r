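#' Parameters of the parallel RLC reference circuit
#'
#' A resistor `R`, capacitor `C`, and leaky inductor (`L` in series with
#' `R_L`) in parallel at one node, reached through an electrode resistance
#' `Re`.  The defaults are the reference circuit used as the ideal-inductor
#' benchmark for channel gating: R = 100 MOhm, C = 200 pF, L = 10 MH,
#' R_L = 30 MOhm, Re = 5 MOhm.
#'
#' @param R_MOhm,C_pF,L_MH,R_L_MOhm,Re_MOhm Component values (all > 0).
#' @return An `rlc_params` object.
#' @export
rlc_params <- function(R_MOhm = 100, C_pF = 200, L_MH = 10, R_L_MOhm = 30,
                       Re_MOhm = 5) {
  vals <- c(R_MOhm, C_pF, L_MH, R_L_MOhm, Re_MOhm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all circuit parameters must be positive")
  structure(list(R = R_MOhm, C = C_pF, L = L_MH, R_L = R_L_MOhm,
                 Re = Re_MOhm),
            class = "rlc_params")
}

#' Analytic impedance of the RLC circuit
#'
#' `Z(f) = Re + [ R || (R_L + j w L) || 1/(j w C) ]` with `w = 2 pi f`.
#' Units work out directly in MOhm with C in pF and L in MH when f is in Hz
#' scaled appropriately; the conversion is handled internally.
#'
#' @param f_Hz Frequencies (Hz, >= 0); vectorized.
#' @param p An `rlc_params`.
#' @return Complex impedance in MOhm.
#' @export
rlc_impedance <- function(f_Hz, p) {
  stopifnot(inherits(p, "rlc_params"))
  if (any(f_Hz < 0)) stop("frequencies must be non-negative")
  w <- 2 * pi * f_Hz                 # rad/s
  # SI: R [Ohm], C [F], L [H]
  R <- p$R * 1e6; RL <- p$R_L * 1e6; Re <- p$Re * 1e6
  C <- p$C * 1e-12; L <- p$L * 1e6
  zl <- RL + 1i * w * L
  y <- 1 / R + 1 / zl + 1i * w * C   # node admittance
  (Re + 1 / y) / 1e6
}

#' Closed-form inductor-branch step response
#'
#' With the node ideally clamped by a voltage step, the change in the
#' leaky-inductor branch current is
#' `dI_L(t) = (step / R_L) * (1 - exp(-t R_L / L))`: zero at the step, an
#' exponential approach with time constant `L / R_L` to the Ohmic plateau
#' `step / R_L`.
#'
#' @param step_mV Voltage-step amplitude (mV).
#' @param t_ms Times since the step (ms); vectorized.
#' @param p An `rlc_params`.
#' @return Change in inductor current (nA).
#' @export
inductor_step_current <- function(step_mV, t_ms, p) {
  stopifnot(inherits(p, "rlc_params"))
  tau_ms <- p$L / (1e-3 * p$R_L)     # MH / MOhm -> s -> ms
  (step_mV / p$R_L) * (1 - exp(-t_ms / tau_ms))
}

#' Simulate the RLC circuit under an arbitrary drive
#'
#' Integrates the two-state circuit (capacitor node voltage, inductor
#' branch current) by backward Euler.  Three clamp variants: `"voltage"`
#' clamps the source side of the electrode resistance (as the circuit is
#' drawn), `"voltage_ideal"` clamps the node itself (bypassing `Re`; the
#' variant matching the closed-form [inductor_step_current()]), and
#' `"current"` injects the drive current into the node.
#'
#' @param drive An `ephys_trace`: a voltage command (mV) for the voltage
#'   modes or a current (interpreted in nA) for current mode.
#' @param p An `rlc_params`.
#' @param mode One of `"voltage"`, `"voltage_ideal"`, `"current"`.
#' @return A data.frame with time (ms), node voltage `Vn_mV`, branch
#'   currents `IL_nA`, `IR_nA`, `IC_nA`, the source current `Isource_nA`,
#'   and the source-side voltage `Vsource_mV`.
#' @export
simulate_rlc <- function(drive, p, mode = c("voltage", "voltage_ideal",
                                            "current")) {
  stopifnot(inherits(drive, "ephys_trace"), inherits(p, "rlc_params"))
  mode <- match.arg(mode)
  res <- rlc_integrate(drive$values, drive$dt, mode, p$R, p$C, p$L, p$R_L,
                       p$Re)
  data.frame(time_ms = trace_time(drive),
             Vn_mV = res$Vn_mV, IL_nA = res$IL_nA, IR_nA = res$IR_nA,
             IC_nA = res$IC_nA, Isource_nA = res$Isource_nA,
             Vsource_mV = res$Vsource_mV)
}
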