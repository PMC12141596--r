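#' Read and validate a scenario configuration
#'
#' A scenario config is a YAML file with a `type` (one of `zap`, `vstep`,
#' `oscillation`, `rlc_step`, `synth_pair`), an optional `cell` section
#' (overrides of the default single-compartment cell), a `channel` name
#' (`kcnq`, `kcnq_inactivation`, `none`, or a path to a parameter file), a
#' `protocol` section, and an optional integer `seed`.  Unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A validated `scenario_config` list.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("type", "cell", "channel", "protocol", "analysis", "seed",
               "label")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  types <- c("zap", "vstep", "oscillation", "rlc_step", "synth_pair")
  if (is.null(cfg$type) || !cfg$type %in% types)
    stop("config 'type' must be one of: ", paste(types, collapse = ", "))
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$channel)) cfg$channel <- "kcnq"
  structure(cfg, class = "scenario_config")
}

# internal: build the cell described by a config
scenario_cell <- function(cfg) {
  channels <- switch(cfg$channel,
    none = list(),
    kcnq = list(kcnq_model()),
    kcnq_inactivation = list(kcnq_inactivation_model()),
    read_channel_params(cfg$channel))
  cellargs <- cfg$cell
  if (is.null(cellargs)) cellargs <- list()
  geom <- cell_geometry(
    diameter_um = if (is.null(cellargs$diameter_um)) 40 else cellargs$diameter_um,
    length_um = if (is.null(cellargs$length_um)) 40 else cellargs$length_um)
  grab <- function(key, default)
    if (is.null(cellargs[[key]])) default else cellargs[[key]]
  cell_model(geometry = geom,
             g_pas = grab("g_pas_S_cm2", 1.4e-5),
             e_pas = grab("e_pas_mV", -60),
             cm = grab("cm_uF_cm2", 5),
             Ra = grab("Ra_Ohm_cm", 100),
             E_K = grab("E_K_mV", -97.5),
             channels = channels)
}

#' Execute a scenario and write its artifact bundle
#'
#' Runs simulate-then-analyze for the configured scenario and writes trace
#' CSVs, a metrics JSON, and a run log (package version, seed, config) to
#' `out_dir`.  Re-running with the same config and seed reproduces the same
#' metrics.
#'
#' @param config A `scenario_config` or a path to one.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the metrics list.
#' @export
run_scenario <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_scenario_config(config) else config
  stopifnot(inherits(cfg, "scenario_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pr <- cfg$protocol
  if (is.null(pr)) pr <- list()
  grab <- function(key, default)
    if (is.null(pr[[key]])) default else pr[[key]]

  metrics <- switch(cfg$type,
    zap = {
      cell <- scenario_cell(cfg)
      spec <- chirp_spec(amplitude_pA = grab("amplitude_pA", 50),
                         f_start_Hz = grab("f_start_Hz", 0),
                         f_end_Hz = grab("f_end_Hz", 40),
                         duration_s = grab("duration_s", 40))
      res <- zap_impedance(cell, holding_mV = grab("holding_mV", -40),
                           spec = spec, dt = grab("dt_ms", 0.025))
      utils::write.csv(res$profile, file.path(out_dir, "impedance.csv"),
                       row.names = FALSE)
      list(resonant_frequency_Hz = res$metrics$resonant_frequency_Hz,
           resonant_strength = res$metrics$resonant_strength,
           Z_at_low_MOhm = res$metrics$Z_at_low_MOhm)
    },
    vstep = {
      cell <- scenario_cell(cfg)
      dt <- grab("dt_ms", 0.01)
      pre <- grab("pre_ms", 2000)
      step <- grab("step_ms", 3000)
      cmds <- build_voltage_steps(grab("holding_mV", -30),
                                  grab("step_mV", -20),
                                  pre_ms = pre, step_ms = step,
                                  post_ms = grab("post_ms", 3000), dt = dt)
      sim <- run_voltage_clamp(cell, cmds[[1]])
      write_trace(sim$response, file.path(out_dir, "current.csv"))
      sm <- step_metrics(sim$conductance, dt = dt, onset_ms = pre,
                         offset_ms = pre + step)
      sm
    },
    oscillation = {
      cell <- scenario_cell(cfg)
      res <- oscillation_response(cell, target_mV = grab("target_mV", -25),
                                  step_s = grab("step_s", 12),
                                  dt = grab("dt_ms", 0.025))
      psd <- power_spectrum(res$V)
      list(oscillating = detect_oscillation(psd),
           peak_freq_Hz = psd$peak_freq_Hz, peak_psd = psd$peak_psd,
           step_pA = res$step_pA)
    },
    rlc_step = {
      p <- rlc_params()
      dt <- grab("dt_ms", 0.05)
      cmds <- build_voltage_steps(0, grab("step_mV", 10),
                                  pre_ms = grab("pre_ms", 200),
                                  step_ms = grab("step_ms", 2000),
                                  post_ms = grab("post_ms", 2000), dt = dt)
      out <- simulate_rlc(cmds[[1]], p, mode = "voltage_ideal")
      utils::write.csv(out[seq(1, nrow(out), by = 20), ],
                       file.path(out_dir, "rlc_step.csv"), row.names = FALSE)
      i_on <- round(grab("pre_ms", 200) / dt) + 1L
      list(IL_plateau_nA = out$IL_nA[round((grab("pre_ms", 200) +
             grab("step_ms", 2000)) / dt)] - out$IL_nA[i_on - 1L],
           tau_ms = p$L / (1e-3 * p$R_L))
    },
    synth_pair = {
      cell <- scenario_cell(cfg)
      cmds <- build_voltage_steps(grab("holding_mV", -40),
                                  grab("step_mV", -30),
                                  pre_ms = grab("pre_ms", 500),
                                  step_ms = grab("step_ms", 1000),
                                  post_ms = grab("post_ms", 500),
                                  dt = grab("dt_ms", 0.05))
      spec <- recording_spec(cell, cmds[[1]],
                             noise_sd_pA = grab("noise_sd_pA", 2),
                             block_fraction = grab("block_fraction", 1),
                             seed = cfg$seed)
      rec <- make_paired_recordings(spec)
      write_trace(rec$control, file.path(out_dir, "control.csv"))
      write_trace(rec$blocked, file.path(out_dir, "blocked.csv"))
      diff <- subtract_blocker(rec$control, rec$blocked)
      list(diff_rms_pA = sqrt(mean(diff$values^2)),
           true_rms_pA = sqrt(mean(rec$channel_current$values^2)))
    })

  meta <- list(package = "kcnqres",
               version = as.character(utils::packageVersion("kcnqres")),
               seed = cfg$seed, type = cfg$type,
               config = unclass(cfg))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(meta, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(metrics)
}
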