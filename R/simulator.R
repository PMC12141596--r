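#' @useDynLib kcnqres, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# internal: assemble C++ channel specs for a cell
cell_cpp_channels <- function(cell) {
  area <- cell_area_cm2(cell)
  lapply(cell$channels, channel_cpp_spec, area_cm2 = area)
}

new_sim_result <- function(command, response, g, m, h, cell) {
  gates <- list()
  if (length(cell$channels)) {
    labs <- vapply(cell$channels, function(ch) ch$label, character(1))
    gates <- lapply(seq_along(cell$channels), function(i) {
      out <- list(m = m[, i])
      if (!is.null(cell$channels[[i]]$inactivation)) out$h <- h[, i]
      out
    })
    names(gates) <- make.unique(labs)
  }
  structure(list(command = command,
                 response = response,
                 conductance = g,   # nS, sum over channels
                 gates = gates,
                 dt = command$dt),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s clamp, %d samples, dt = %g ms\n",
              if (x$command$kind == "voltage") "voltage" else "current",
              length(x$command$values), x$dt))
  cat(sprintf("  response: %s in [%.4g, %.4g] %s; g in [%.4g, %.4g] nS\n",
              x$response$kind, min(x$response$values), max(x$response$values),
              x$response$units, min(x$conductance), max(x$conductance)))
  invisible(x)
}

#' Run a voltage-clamp simulation
#'
#' The command potential is imposed exactly (ideal clamp, no series
#' resistance); gates relax analytically against the piecewise-constant
#' command and the reported current is the ionic channel current
#' `sum_i g_i(t) * (V(t) - E_K)` -- the capacitive transient of an ideal
#' clamp is excluded.
#'
#' @param cell A `cell_model` (its channels are simulated; leak is not part
#'   of the reported channel current).
#' @param command An `ephys_trace` of kind voltage.
#' @return A `sim_result` with `response` the channel current (pA),
#'   `conductance` (nS) and per-channel gate traces.
#' @export
run_voltage_clamp <- function(cell, command) {
  stopifnot(inherits(cell, "cell_model"))
  if (!inherits(command, "ephys_trace") || command$kind != "voltage")
    stop("command must be a voltage trace")
  res <- vc_integrate(command$values, command$dt, cell_cpp_channels(cell),
                      cell$E_K)
  new_sim_result(command,
                 ephys_trace(res$current_pA, command$dt, "current",
                             t0 = command$t0),
                 res$g_nS, res$m, res$h, cell)
}

#' Run a current-clamp simulation
#'
#' Integrates `cm_tot dV/dt = -g_pas_tot (V - e_pas) - sum_i g_i (V - E_K)
#' + I_inject` with exponential-Euler gate updates and a backward-Euler
#' voltage step (operator splitting), which is stable at the default
#' dt of 0.01-0.05 ms.
#'
#' @param cell A `cell_model`.
#' @param inject An `ephys_trace` of kind current (pA).
#' @param v0 Initial membrane potential (mV); gates start at their steady
#'   state for `v0`.
#' @return A `sim_result` with `response` the membrane potential (mV).
#' @export
run_current_clamp <- function(cell, inject, v0 = -60) {
  stopifnot(inherits(cell, "cell_model"))
  if (!inherits(inject, "ephys_trace") || inject$kind != "current")
    stop("inject must be a current trace")
  res <- cc_integrate(inject$values, inject$dt, v0, total_capacitance(cell),
                      total_leak_conductance(cell), cell$e_pas,
                      cell_cpp_channels(cell), cell$E_K)
  new_sim_result(inject,
                 ephys_trace(res$V_mV, inject$dt, "voltage", t0 = inject$t0),
                 res$g_nS, res$m, res$h, cell)
}

#' Steady-state conductance/current family from a voltage-step protocol
#'
#' Runs one voltage-clamp sweep per step level and summarizes the plateau
#' (mean over the last fraction `plateau_frac` of the step epoch).
#'
#' @param cell A `cell_model`.
#' @param holding_mV Holding potential (mV).
#' @param step_levels_mV Step levels (mV), one sweep each.
#' @param pre_ms,step_ms Epoch durations (ms).
#' @param dt Sample interval (ms).
#' @param plateau_frac Fraction of the step used for the plateau mean.
#' @return A data.frame with columns `V_mV`, `I_plateau_pA`, `g_plateau_nS`
#'   and attribute `sims` holding the per-sweep `sim_result`s.
#' @export
run_iv_family <- function(cell, holding_mV = -80,
                          step_levels_mV = seq(-70, -10, by = 10),
                          pre_ms = 1000, step_ms = 3000, dt = 0.01,
                          plateau_frac = 0.1) {
  cmds <- build_voltage_steps(holding_mV, step_levels_mV, pre_ms = pre_ms,
                              step_ms = step_ms, post_ms = dt, dt = dt)
  sims <- lapply(cmds, function(cmd) run_voltage_clamp(cell, cmd))
  n_pre <- round(pre_ms / dt)
  n_step <- round(step_ms / dt)
  idx <- (n_pre + n_step - ceiling(plateau_frac * n_step) + 1):(n_pre + n_step)
  out <- data.frame(
    V_mV = step_levels_mV,
    I_plateau_pA = vapply(sims, function(s) mean(s$response$values[idx]),
                          numeric(1)),
    g_plateau_nS = vapply(sims, function(s) mean(s$conductance[idx]),
                          numeric(1)))
  rownames(out) <- NULL
  attr(out, "sims") <- sims
  out
}

#' Simulate the voltage response to a ZAP chirp at a holding potential
#'
#' Injects the steady bias current that holds the cell at `holding_mV`,
#' waits a settling epoch so gates equilibrate, then superimposes the chirp.
#' The analysis window covers the chirp plus a short zero-stimulus decay
#' tail (`tail_ms`) so the response transient decays inside the window
#' rather than being truncated, which would bias the spectral ratio.
#'
#' @param cell A `cell_model`.
#' @param holding_mV Target holding potential (mV).
#' @param spec A `chirp_spec`.
#' @param dt Sample interval (ms).
#' @param settle_ms Settling epoch before the chirp (ms).
#' @param tail_ms Post-chirp decay tail included in the analysis window (ms).
#' @return List with `V` (voltage trace over chirp + tail), `I` (stimulus
#'   trace over the same window, zero during the tail), and the full `sim`
#'   result.
#' @export
zap_response <- function(cell, holding_mV = -40, spec = chirp_spec(),
                         dt = 0.025, settle_ms = 2000, tail_ms = 2000) {
  bias <- holding_current(cell, holding_mV)
  chirp <- build_chirp(spec, dt)
  n_settle <- round(settle_ms / dt)
  n_tail <- round(tail_ms / dt)
  stim <- c(chirp$values, rep(0, n_tail))
  inject <- ephys_trace(c(rep(bias, n_settle), bias + stim), dt, "current")
  sim <- run_current_clamp(cell, inject, v0 = holding_mV)
  i0 <- n_settle + 1L
  n <- length(stim)
  V <- ephys_trace(sim$response$values[i0:(i0 + n - 1L)], dt, "voltage")
  list(V = V, I = ephys_trace(stim, dt, "current"), sim = sim,
       settle_n = n_settle, bias_pA = bias, cell = cell)
}

#' Simulate a depolarizing current step for oscillation analysis
#'
#' From rest (zero injection), steps the injected current to the level that
#' would hold the cell at `target_mV` in steady state, and returns the
#' voltage trace of the analysis window (the step epoch minus an initial
#' charging transient).
#'
#' @param cell A `cell_model`.
#' @param target_mV Steady-state plateau the step current is sized for (mV).
#' @param rest_s Pre-step epoch at zero injection (s).
#' @param step_s Step duration (s).
#' @param discard_s Initial part of the step excluded from analysis (s).
#' @param dt Sample interval (ms).
#' @return List with `V` (analysis-window voltage trace), `step_pA`, and the
#'   full `sim`.
#' @export
oscillation_response <- function(cell, target_mV = -25, rest_s = 2,
                                 step_s = 12, discard_s = 2, dt = 0.025) {
  step_pA <- holding_current(cell, target_mV)
  n_rest <- round(rest_s * 1000 / dt)
  n_step <- round(step_s * 1000 / dt)
  inject <- ephys_trace(c(rep(0, n_rest), rep(step_pA, n_step)), dt, "current")
  sim <- run_current_clamp(cell, inject, v0 = cell$e_pas)
  i0 <- n_rest + round(discard_s * 1000 / dt) + 1L
  V <- ephys_trace(sim$response$values[i0:length(inject$values)], dt,
                   "voltage")
  list(V = V, step_pA = step_pA, sim = sim)
}
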