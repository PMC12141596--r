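#' Impedance profile from a stimulus/response trace pair
#'
#' Computes the complex impedance `Z(f) = FFT(V) / FFT(I)` at each FFT bin
#' and its magnitude `|Z(f)| = sqrt(Re^2 + Im^2)`.  Both traces are
#' de-meaned first.  Bins where the stimulus power `|FFT(I)|` falls below
#' `power_floor` times its in-band maximum are masked (dropped), not
#' divided, to avoid blow-ups outside the stimulus band.
#'
#' @param V Voltage response trace (mV).
#' @param I Stimulus current trace (pA); same length and dt as `V`.
#' @param f_max_Hz Upper frequency bound of the returned profile (Hz).
#' @param power_floor Stimulus-power mask threshold (fraction of band max).
#' @return An `impedance_profile`: data.frame with columns `freq_Hz`,
#'   `Z_re_MOhm`, `Z_im_MOhm`, `Z_mag_MOhm`.
#' @export
compute_impedance <- function(V, I, f_max_Hz = 100, power_floor = 0.01) {
  check_aligned(V, I)
  if (V$kind != "voltage" || I$kind != "current")
    stop("expected a voltage response and a current stimulus")
  n <- length(V$values)
  fs <- 1000 / V$dt                      # Hz
  fv <- stats::fft(V$values - mean(V$values))
  fi <- stats::fft(I$values - mean(I$values))
  nb <- floor(n / 2)                     # positive-frequency bins
  freqs <- (1:nb) * fs / n
  keep_f <- freqs <= f_max_Hz
  fv <- fv[2:(nb + 1)][keep_f]
  fi <- fi[2:(nb + 1)][keep_f]
  freqs <- freqs[keep_f]
  pw <- Mod(fi)
  keep_p <- pw >= power_floor * max(pw)
  # mV / pA = GOhm -> MOhm
  z <- (fv[keep_p] / fi[keep_p]) * 1000
  structure(data.frame(freq_Hz = freqs[keep_p],
                       Z_re_MOhm = Re(z),
                       Z_im_MOhm = Im(z),
                       Z_mag_MOhm = Mod(z)),
            class = c("impedance_profile", "data.frame"))
}

#' Average forward and phase-reversed impedance profiles
#'
#' Pointwise mean of the two magnitude spectra (the convention used
#' throughout this package for combining the forward and reversed chirp
#' runs).  Set `complex_mean = TRUE` to average the complex impedances
#' instead and recompute the magnitude.
#'
#' @param p1,p2 `impedance_profile`s on identical frequency grids.
#' @param complex_mean Average complex values rather than magnitudes.
#' @return An `impedance_profile`.
#' @export
average_forward_reverse <- function(p1, p2, complex_mean = FALSE) {
  stopifnot(inherits(p1, "impedance_profile"), inherits(p2, "impedance_profile"))
  if (nrow(p1) != nrow(p2) || any(abs(p1$freq_Hz - p2$freq_Hz) >
                                  1e-9 * (p1$freq_Hz + 1e-12)))
    stop("impedance profiles are on different frequency grids")
  out <- p1
  out$Z_re_MOhm <- (p1$Z_re_MOhm + p2$Z_re_MOhm) / 2
  out$Z_im_MOhm <- (p1$Z_im_MOhm + p2$Z_im_MOhm) / 2
  if (complex_mean) {
    out$Z_mag_MOhm <- sqrt(out$Z_re_MOhm^2 + out$Z_im_MOhm^2)
  } else {
    out$Z_mag_MOhm <- (p1$Z_mag_MOhm + p2$Z_mag_MOhm) / 2
  }
  out
}

#' Resonant frequency and strength from an impedance profile
#'
#' The resonant frequency is the frequency (above 0.5 Hz) at which the
#' impedance magnitude is maximal; the resonant strength is the ratio of
#' that maximum to the impedance at the bin nearest 0.5 Hz.  For a
#' non-resonant (monotonically decreasing) profile the resonant frequency
#' is the 0.5 Hz bin itself and the strength is 1.
#'
#' @param profile An `impedance_profile`.
#' @param f_low_Hz,f_high_Hz Search band (Hz).
#' @return A `resonance_metrics` list: `resonant_frequency_Hz`,
#'   `resonant_strength`, `Z_at_low_MOhm`, `Z_peak_MOhm`.
#' @export
resonance_metrics <- function(profile, f_low_Hz = 0.5, f_high_Hz = 40) {
  stopifnot(inherits(profile, "impedance_profile"))
  in_band <- which(profile$freq_Hz >= f_low_Hz - 1e-9 &
                   profile$freq_Hz <= f_high_Hz + 1e-9)
  if (!length(in_band)) stop("no frequency bins inside the search band")
  i_low <- in_band[which.min(abs(profile$freq_Hz[in_band] - f_low_Hz))]
  i_max <- in_band[which.max(profile$Z_mag_MOhm[in_band])]
  z_low <- profile$Z_mag_MOhm[i_low]
  structure(list(resonant_frequency_Hz = profile$freq_Hz[i_max],
                 resonant_strength = profile$Z_mag_MOhm[i_max] / z_low,
                 Z_at_low_MOhm = z_low,
                 Z_peak_MOhm = profile$Z_mag_MOhm[i_max]),
            class = "resonance_metrics")
}

#' @export
print.resonance_metrics <- function(x, ...) {
  cat(sprintf(
    "<resonance_metrics> f_res = %.3g Hz, strength = %.3f (|Z| %.1f -> %.1f MOhm)\n",
    x$resonant_frequency_Hz, x$resonant_strength, x$Z_at_low_MOhm,
    x$Z_peak_MOhm))
  invisible(x)
}

#' Full ZAP impedance analysis of a model cell
#'
#' Simulates the forward and phase-reversed chirp at a holding potential,
#' computes both impedance profiles, averages them, and extracts the
#' resonance metrics.
#'
#' @inheritParams zap_response
#' @param f_low_Hz,f_high_Hz Resonance search band (Hz).
#' @return List with `profile` (averaged), `metrics`, and the two
#'   single-direction profiles `forward`, `reverse`.
#' @export
zap_impedance <- function(cell, holding_mV = -40, spec = chirp_spec(),
                          dt = 0.025, settle_ms = 2000, f_low_Hz = 0.5,
                          f_high_Hz = 40) {
  fw <- zap_response(cell, holding_mV, spec, dt, settle_ms)
  rspec <- spec
  rspec$phase_sign <- -spec$phase_sign
  rv <- zap_response(cell, holding_mV, rspec, dt, settle_ms)
  p_fw <- compute_impedance(fw$V, fw$I, f_max_Hz = f_high_Hz * 1.5)
  p_rv <- compute_impedance(rv$V, rv$I, f_max_Hz = f_high_Hz * 1.5)
  profile <- average_forward_reverse(p_fw, p_rv)
  list(profile = profile,
       metrics = resonance_metrics(profile, f_low_Hz, f_high_Hz),
       forward = p_fw, reverse = p_rv, sim_forward = fw$sim)
}

#' Channel conductance versus instantaneous chirp frequency
#'
#' From a chirp current-clamp simulation, computes the per-cycle mean total
#' channel conductance, normalized to the pre-stimulus baseline, indexed by
#' the instantaneous frequency at each cycle's midpoint.  Cycle boundaries
#' are the phase crossings of the chirp's analytic phase.
#'
#' @param zap Result of [zap_response()].
#' @param spec The `chirp_spec` used for the run.
#' @return Data.frame with columns `freq_Hz` and `g_rel` (baseline-relative
#'   mean conductance per cycle).
#' @export
conductance_vs_frequency <- function(zap, spec = chirp_spec()) {
  sim <- zap$sim
  n_settle <- zap$settle_n
  g <- sim$conductance
  g0 <- mean(g[max(1, n_settle - 100):n_settle])   # pre-stimulus baseline
  if (g0 < 1e-9) {
    # no voltage-gated conductance at baseline (e.g. a passive-only cell):
    # normalize the total membrane conductance instead, which is constant
    leak <- total_leak_conductance(zap$cell)
    g <- g + leak
    g0 <- g0 + leak
  }
  dt <- sim$dt
  n <- min(length(sim$command$values) - n_settle,
           round(spec$duration_s * 1000 / dt))   # chirp window only
  t_s <- (seq_len(n) - 1) * dt / 1000
  phase <- spec$f_start_Hz * t_s +
    (spec$f_end_Hz - spec$f_start_Hz) * t_s^2 / (2 * spec$duration_s)
  cyc <- floor(phase)                    # cycle index per sample
  gw <- g[(n_settle + 1):(n_settle + n)]
  ncyc <- max(cyc)
  keep <- cyc >= 1 & cyc <= ncyc - 1     # complete interior cycles only
  g_mean <- tapply(gw[keep], cyc[keep], mean)
  t_mid <- tapply(t_s[keep], cyc[keep], stats::median)
  data.frame(freq_Hz = chirp_instantaneous_frequency(spec, as.numeric(t_mid)),
             g_rel = as.numeric(g_mean) / g0)
}
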