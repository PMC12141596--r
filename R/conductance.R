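#' Conductance trace from a current trace and driving force
#'
#' `g(t) = I(t) / (V(t) - E_K)`.  Samples where the driving force is within
#' `guard_mV` of zero are masked to `NA` rather than divided (singularity
#' guard).  For experimental-style analyses the K+ reversal convention is
#' -98 mV; simulation-side analyses use -97.5 mV.
#'
#' @param I Current trace (pA).
#' @param V Voltage: either an `ephys_trace` aligned with `I` or a scalar
#'   holding potential (mV).
#' @param E_K Potassium reversal potential (mV).
#' @param guard_mV Driving-force singularity guard (mV).
#' @return Numeric vector of conductances (nS), `NA` at masked samples.
#' @export
conductance_trace <- function(I, V, E_K = -98, guard_mV = 1) {
  stopifnot(inherits(I, "ephys_trace"), I$kind == "current")
  if (inherits(V, "ephys_trace")) {
    check_aligned(I, V)
    v <- V$values
  } else {
    v <- rep(as.numeric(V), length(I$values))
  }
  drive <- v - E_K
  g <- I$values / drive
  g[abs(drive) < guard_mV] <- NA_real_
  g
}

#' Blocker-subtraction difference current
#'
#' Pointwise `control - blocked`, the standard isolation of a
#' pharmacologically sensitive current from paired sweeps.
#'
#' @param control,blocked Aligned current traces (pA).
#' @return An `ephys_trace` of the difference current.
#' @export
subtract_blocker <- function(control, blocked) {
  check_aligned(control, blocked)
  ephys_trace(control$values - blocked$values, control$dt, control$kind,
              t0 = control$t0)
}

#' Opposing-transient and plateau metrics at a conductance step
#'
#' Quantifies the step-transition behaviour of a conductance trace: the
#' steady conductance before the step (mean of the last `steady_frac` of the
#' pre epoch), the plateau during the step (same convention), and the signed
#' opposing transient within `transient_ms` after each transition.  For a
#' depolarizing step in an outward conductance, the opposing change is a
#' *decrease* at onset (reported relative to the pre-step steady level, so
#' negative) and an *increase* at offset (relative to the plateau, so
#' positive); a channel without the opposing change scores approximately
#' zero on both even though it activates slowly toward the plateau.  Set
#' `depolarizing = FALSE` to flip the search directions for a
#' hyperpolarizing step.
#'
#' @param g Numeric conductance vector (nS) or `ephys_trace`-like values.
#' @param dt Sample interval (ms) (ignored if `g` is an `ephys_trace`).
#' @param onset_ms,offset_ms Step onset / offset times (ms from trace start).
#' @param transient_ms Transient search window after each transition (ms).
#' @param steady_frac Fraction of each epoch used for steady-state means.
#' @param depolarizing Direction of the voltage step (default depolarizing).
#' @return A `step_metrics` list: `pre_steady_g`, `plateau_g`,
#'   `onset_transient_rel`, `offset_transient_rel`.
#' @export
step_metrics <- function(g, dt = NULL, onset_ms, offset_ms,
                         transient_ms = 50, steady_frac = 0.2,
                         depolarizing = TRUE) {
  if (inherits(g, "ephys_trace")) {
    dt <- g$dt
    g <- g$values
  }
  if (is.null(dt)) stop("dt is required when g is a bare vector")
  n <- length(g)
  i_on <- round(onset_ms / dt) + 1L
  i_off <- round(offset_ms / dt) + 1L
  n_tr <- round(transient_ms / dt)
  if (i_off + n_tr > n || i_on <= 1L)
    stop("transient window exceeds the trace")

  pre_idx <- max(1L, i_on - ceiling(steady_frac * (i_on - 1L))):(i_on - 1L)
  pre_g <- mean(g[pre_idx], na.rm = TRUE)
  step_len <- i_off - i_on
  plat_idx <- (i_off - ceiling(steady_frac * step_len)):(i_off - 1L)
  plateau_g <- mean(g[plat_idx], na.rm = TRUE)

  # signed opposing-direction extremum relative to the reference level
  transient_rel <- function(idx, ref, direction) {
    dev <- g[idx] - ref
    ext <- if (direction < 0) min(dev, na.rm = TRUE)
           else max(dev, na.rm = TRUE)
    ext / ref
  }
  on_dir <- if (depolarizing) -1 else 1
  list(pre_steady_g = pre_g,
       plateau_g = plateau_g,
       onset_transient_rel = transient_rel(i_on:(i_on + n_tr), pre_g, on_dir),
       offset_transient_rel = transient_rel(i_off:(i_off + n_tr), plateau_g,
                                            -on_dir))
}

#' Amplitude metrics of a sinusoidal-clamp current
#'
#' The amplitude is half the bottom-to-top magnitude of the steady
#' sinusoidal current; outward and inward amplitudes are measured from the
#' pre-stimulus baseline (mean over the holding window).  The first cycle
#' after stimulus onset is discarded as transient.
#'
#' @param I Current trace (pA) covering the holding epoch and the sinusoid.
#' @param baseline_window_ms Length-2 vector: the pre-stimulus window (ms).
#' @param stim_onset_ms Time of sinusoid onset (ms).
#' @param freq_Hz Sinusoid frequency (Hz), used to discard the first cycle.
#' @return List with `amplitude_pA`, `outward_amp_pA`, `inward_amp_pA`,
#'   `baseline_pA`.
#' @export
sinusoid_metrics <- function(I, baseline_window_ms, stim_onset_ms, freq_Hz) {
  stopifnot(inherits(I, "ephys_trace"), I$kind == "current")
  t <- trace_time(I)
  base_idx <- t >= baseline_window_ms[1] & t <= baseline_window_ms[2]
  if (!any(base_idx)) stop("baseline window is outside the trace")
  baseline <- mean(I$values[base_idx])
  cycle_ms <- 1000 / freq_Hz
  steady_idx <- t >= stim_onset_ms + cycle_ms
  if (sum(steady_idx) < cycle_ms / I$dt)
    stop("no steady cycle after the transient: trace too short")
  y <- I$values[steady_idx]
  list(amplitude_pA = (max(y) - min(y)) / 2,
       outward_amp_pA = max(y) - baseline,
       inward_amp_pA = baseline - min(y),
       baseline_pA = baseline)
}

#' Fit a single exponential to a trace segment
#'
#' Least-squares fit of `y(t) = offset + amplitude * exp(-t / tau)` by
#' Levenberg-Marquardt, initialized from the tail mean (offset) and a
#' log-linear regression of `|y - offset|` (tau).
#'
#' @param y Numeric vector (the segment), or an `ephys_trace`.
#' @param dt Sample interval (ms) (ignored if `y` is an `ephys_trace`).
#' @return An `exp_fit` list: `tau_ms`, `amplitude`, `offset`, `sigma`
#'   (residual standard deviation).
#' @export
fit_exponential <- function(y, dt = NULL) {
  if (inherits(y, "ephys_trace")) {
    dt <- y$dt
    y <- y$values
  }
  if (is.null(dt)) stop("dt is required when y is a bare vector")
  n <- length(y)
  if (n < 5L) stop("segment too short for an exponential fit")
  t <- (seq_len(n) - 1) * dt

  offset0 <- mean(y[max(1, n - ceiling(n / 10)):n])
  dev <- y - offset0
  s <- sign(mean(dev[1:max(1, ceiling(n / 10))]))
  # log-linear slope over the early, signal-dominated part of the decay;
  # clamp the start value so the initial Jacobian stays well-conditioned
  pos <- which(s * dev > 0.2 * max(s * dev))
  tau0 <- if (length(pos) > 3) {
    fitl <- stats::lm(log(s * dev[pos]) ~ t[pos])
    unname(-1 / stats::coef(fitl)[2])
  } else {
    t[n] / 5
  }
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- t[n] / 5
  tau0 <- min(max(tau0, dt), t[n])
  amp0 <- y[1] - offset0

  d <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ offset + amplitude * exp(-t / tau), data = d,
                      start = list(offset = offset0, amplitude = amp0,
                                   tau = tau0),
                      lower = c(-Inf, -Inf, 1e-9),
                      upper = c(Inf, Inf, 10 * t[n]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  structure(list(tau_ms = unname(cf["tau"]),
                 amplitude = unname(cf["amplitude"]),
                 offset = unname(cf["offset"]),
                 sigma = stats::sigma(fit)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> tau = %.4g ms, amplitude = %.4g, offset = %.4g\n",
              x$tau_ms, x$amplitude, x$offset))
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) {
  c(tau_ms = object$tau_ms, amplitude = object$amplitude,
    offset = object$offset)
}

#' 10-90% rise time of a single exponential
#'
#' For `y = offset + A (1 - exp(-t/tau))`, the time between 10% and 90% of
#' the full excursion is `tau * ln 9`.
#'
#' @param tau_ms Time constant (ms).
#' @return Rise time (ms).
#' @export
rise_time_10_90 <- function(tau_ms) tau_ms * log(9)

#' Fit a Boltzmann activation curve to conductance-voltage data
#'
#' Nonlinear least squares for
#' `G / G_max = 1 / (1 + exp[(V_half - V) / k])`.  With
#' `relative = TRUE` the data are treated as already normalized and `G_max`
#' is fixed at 1.
#'
#' @param V_mV Voltage levels (mV); at least 4, spanning the transition.
#' @param G Conductances (nS, or relative units).
#' @param relative Fix `G_max = 1` (relative-conductance mode).
#' @return A `boltzmann_fit` list: `V_half_mV`, `k_mV`, `G_max`, `sigma`,
#'   and `low_confidence` (TRUE when the data do not span the transition).
#' @export
fit_boltzmann <- function(V_mV, G, relative = FALSE) {
  stopifnot(length(V_mV) == length(G))
  if (length(V_mV) < 4L) stop("need at least 4 voltage levels")
  d <- data.frame(V = V_mV, G = G)
  gmax0 <- max(G)
  vhalf0 <- stats::approx(G / gmax0, V_mV, xout = 0.5, ties = mean)$y
  if (is.na(vhalf0)) vhalf0 <- stats::median(V_mV)
  converged <- TRUE
  fit <- withCallingHandlers(
    if (relative) {
      minpack.lm::nlsLM(G ~ 1 / (1 + exp((vhalf - V) / k)), data = d,
                        start = list(vhalf = vhalf0, k = 8),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(G ~ gmax / (1 + exp((vhalf - V) / k)), data = d,
                        start = list(gmax = gmax0, vhalf = vhalf0, k = 8),
                        lower = c(0, -Inf, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    warning = function(w) {
      # iteration-limit warnings mean the data barely constrain the curve
      # (typically non-spanning G-V data); fold that into the flag
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  gmax_fit <- if (relative) 1 else unname(cf["gmax"])
  rng <- range(G) / gmax_fit
  structure(list(V_half_mV = unname(cf["vhalf"]),
                 k_mV = unname(cf["k"]),
                 G_max = gmax_fit,
                 sigma = stats::sigma(fit),
                 low_confidence = !converged || rng[1] > 0.25 || rng[2] < 0.75),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> V_half = %.2f mV, k = %.2f mV, G_max = %.4g%s\n",
              x$V_half_mV, x$k_mV, x$G_max,
              if (x$low_confidence) " (low confidence: data do not span the transition)"
              else ""))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(V_half_mV = object$V_half_mV, k_mV = object$k_mV, G_max = object$G_max)
}
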