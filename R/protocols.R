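#' Chirp (ZAP) stimulus specification
#'
#' Constant-amplitude sinusoidal current whose instantaneous frequency sweeps
#' linearly from `f_start` to `f_end` over `duration`.  The standard probe
#' is 50 pA, 0 to 40 Hz over 40 s.
#'
#' @param amplitude_pA Peak amplitude (pA).
#' @param f_start_Hz,f_end_Hz Start / end frequency (Hz, `f_end >= f_start >= 0`).
#' @param duration_s Sweep duration (s, > 0).
#' @param phase_sign +1 for the forward chirp, -1 for the phase-reversed twin.
#' @return A `chirp_spec` object.
#' @export
chirp_spec <- function(amplitude_pA = 50, f_start_Hz = 0, f_end_Hz = 40,
                       duration_s = 40, phase_sign = 1) {
  stopifnot(duration_s > 0, f_end_Hz >= f_start_Hz, f_start_Hz >= 0,
            phase_sign %in% c(-1, 1))
  structure(list(amplitude_pA = amplitude_pA, f_start_Hz = f_start_Hz,
                 f_end_Hz = f_end_Hz, duration_s = duration_s,
                 phase_sign = phase_sign),
            class = "chirp_spec")
}

#' Build a chirp current trace
#'
#' `I(t) = s * A * sin(2 pi (f0 t + (f1 - f0) t^2 / (2 T)))`, starting at
#' baseline (sine phase 0) so the stimulus begins without a step.
#'
#' @param spec A `chirp_spec`.
#' @param dt Sample interval (ms); must resolve `f_end`
#'   (`dt <= 1 / (20 * f_end)` seconds).
#' @return An `ephys_trace` of kind current.
#' @export
build_chirp <- function(spec, dt = 0.025) {
  stopifnot(inherits(spec, "chirp_spec"))
  if (spec$f_end_Hz > 0 && dt * 1e-3 > 1 / (20 * spec$f_end_Hz))
    stop("dt = ", dt, " ms undersamples a ", spec$f_end_Hz, " Hz chirp")
  n <- round(spec$duration_s * 1000 / dt)
  t_s <- (seq_len(n) - 1) * dt / 1000
  phase <- 2 * pi * (spec$f_start_Hz * t_s +
                     (spec$f_end_Hz - spec$f_start_Hz) * t_s^2 /
                       (2 * spec$duration_s))
  ephys_trace(spec$phase_sign * spec$amplitude_pA * sin(phase), dt, "current")
}

#' Instantaneous frequency of a chirp at given times
#'
#' @param spec A `chirp_spec`.
#' @param t_s Times from chirp onset (s).
#' @return Frequency in Hz, linear in time.
#' @export
chirp_instantaneous_frequency <- function(spec, t_s) {
  spec$f_start_Hz +
    (spec$f_end_Hz - spec$f_start_Hz) * t_s / spec$duration_s
}

#' Build a family of voltage-step command traces
#'
#' Each sweep holds at `holding_mV`, steps to one level for `step_ms`, and
#' returns to holding for `post_ms`.
#'
#' @param holding_mV Holding potential (mV).
#' @param step_levels_mV Vector of step levels (mV), one sweep each.
#' @param pre_ms,step_ms,post_ms Epoch durations (ms, > 0).
#' @param dt Sample interval (ms).
#' @return Named list of `ephys_trace` voltage commands, one per level.
#' @export
build_voltage_steps <- function(holding_mV, step_levels_mV,
                                pre_ms = 1000, step_ms = 1000,
                                post_ms = 1000, dt = 0.01) {
  stopifnot(pre_ms > 0, step_ms > 0, post_ms > 0)
  n_pre <- round(pre_ms / dt)
  n_step <- round(step_ms / dt)
  n_post <- round(post_ms / dt)
  out <- lapply(step_levels_mV, function(lv) {
    ephys_trace(c(rep(holding_mV, n_pre), rep(lv, n_step),
                  rep(holding_mV, n_post)), dt, "voltage")
  })
  names(out) <- sprintf("%+g_mV", step_levels_mV)
  out
}

#' Build a sinusoidal voltage-clamp command
#'
#' `V(t) = holding + amplitude * sin(2 pi f t)` for an integer number of
#' cycles, preceded by a holding epoch.
#'
#' @param holding_mV Holding potential (mV).
#' @param amplitude_mV Sinusoid amplitude (mV).
#' @param freq_Hz Frequency (Hz, > 0).
#' @param n_cycles Integer number of cycles.
#' @param pre_ms Pre-stimulus holding epoch (ms).
#' @param dt Sample interval (ms).
#' @return An `ephys_trace` of kind voltage.
#' @export
build_sinusoid_vc <- function(holding_mV = -40, amplitude_mV = 15,
                              freq_Hz = 0.5, n_cycles = 2, pre_ms = 1000,
                              dt = 0.01) {
  stopifnot(freq_Hz > 0, n_cycles >= 1)
  n_pre <- round(pre_ms / dt)
  n_sin <- round(n_cycles * 1000 / (freq_Hz * dt))
  t_s <- (seq_len(n_sin) - 1) * dt / 1000
  ephys_trace(c(rep(holding_mV, n_pre),
                holding_mV + amplitude_mV * sin(2 * pi * freq_Hz * t_s)),
              dt, "voltage")
}
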