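test_that("conductance_trace divides by driving force with a guard", {
  dt <- 1
  I0 <- ephys_trace(rep(0, 100), dt, "current")
  expect_true(all(conductance_trace(I0, -40, E_K = -98) == 0))
  I1 <- ephys_trace(rep(58, 100), dt, "current")
  expect_true(all(conductance_trace(I1, -40, E_K = -98) == 1))
  # a voltage trace crossing E_K gives masked samples, never infinities
  V <- ephys_trace(seq(-100, -96, length.out = 100), dt, "voltage")
  I <- ephys_trace(rep(10, 100), dt, "current")
  g <- conductance_trace(I, V, E_K = -98)
  expect_true(all(is.na(g) | is.finite(g)))
  expect_true(any(is.na(g)))
  # round trip with channel_current is the identity away from E_K
  gs <- runif(50, 0, 10)
  Ir <- ephys_trace(channel_current(gs, -40, -98), dt, "current")
  expect_equal(conductance_trace(Ir, -40, E_K = -98), gs)
})

test_that("blocker subtraction is exact, linear and antisymmetric", {
  cmd <- build_voltage_steps(-40, -30, pre_ms = 200, step_ms = 400,
                             post_ms = 200, dt = 0.05)[[1]]
  spec0 <- recording_spec(cell_kcnq(), cmd, noise_sd_pA = 0,
                          block_fraction = 1, seed = 1)
  rec <- make_paired_recordings(spec0)
  diff <- subtract_blocker(rec$control, rec$blocked)
  expect_equal(diff$values, rec$channel_current$values, tolerance = 1e-12)
  # partial block recovers the blocked fraction of the channel current
  spec08 <- recording_spec(cell_kcnq(), cmd, noise_sd_pA = 0,
                           block_fraction = 0.8, seed = 1)
  rec08 <- make_paired_recordings(spec08)
  diff08 <- subtract_blocker(rec08$control, rec08$blocked)
  expect_equal(diff08$values, 0.8 * rec$channel_current$values,
               tolerance = 1e-12)
  # antisymmetry
  back <- subtract_blocker(rec$blocked, rec$control)
  expect_equal(back$values, -diff$values)
  expect_equal(subtract_blocker(rec$control, rec$control)$values,
               rep(0, length(cmd$values)))
})

test_that("step metrics report signed opposing transients", {
  # constructed fixture: flat 1 nS with an injected dip to 0.8 at onset
  dt <- 1
  g <- rep(1, 1000)
  g[301:310] <- 0.8
  sm <- step_metrics(g, dt = dt, onset_ms = 300, offset_ms = 700)
  expect_equal(sm$onset_transient_rel, -0.2)
  expect_equal(sm$pre_steady_g, 1)
  expect_error(step_metrics(g, dt = dt, onset_ms = 300, offset_ms = 990),
               "exceeds")

  # model contrast: no opposing change without inactivation; signed
  # opposing transients with it
  dtm <- 0.02
  cmd <- build_voltage_steps(-30, -20, pre_ms = 2000, step_ms = 2000,
                             post_ms = 500, dt = dtm)[[1]]
  smq <- step_metrics(run_voltage_clamp(cell_kcnq(), cmd)$conductance,
                      dt = dtm, onset_ms = 2000, offset_ms = 4000)
  expect_lt(abs(smq$onset_transient_rel), 0.02)
  expect_lt(abs(smq$offset_transient_rel), 0.02)
  smi <- step_metrics(run_voltage_clamp(cell_kcnqi(), cmd)$conductance,
                      dt = dtm, onset_ms = 2000, offset_ms = 4000)
  expect_lt(smi$onset_transient_rel, -0.05)
  expect_gt(smi$offset_transient_rel, 0.05)
})

test_that("sinusoid metrics split outward and inward amplitudes", {
  dt <- 1
  t <- (0:9999) * dt / 1000
  pure <- ephys_trace(c(rep(0, 2000), 40 * sin(2 * pi * 1 * t[1:8000])),
                      dt, "current")
  m <- sinusoid_metrics(pure, baseline_window_ms = c(0, 1999),
                        stim_onset_ms = 2000, freq_Hz = 1)
  expect_equal(m$amplitude_pA, 40, tolerance = 1e-3)
  expect_equal(m$outward_amp_pA, 40, tolerance = 1e-3)
  expect_equal(m$inward_amp_pA, 40, tolerance = 1e-3)
  # an offset on the stimulus epoch shifts outward/inward oppositely but
  # leaves the amplitude unchanged
  off <- ephys_trace(pure$values + c(rep(0, 2000), rep(10, 8000)), dt,
                     "current")
  mo <- sinusoid_metrics(off, c(0, 1999), 2000, 1)
  expect_equal(mo$amplitude_pA, m$amplitude_pA)
  expect_equal(mo$outward_amp_pA, m$outward_amp_pA + 10, tolerance = 1e-3)
  expect_equal(mo$inward_amp_pA, m$inward_amp_pA - 10, tolerance = 1e-3)

  # KCNQ difference current at 0.5 Hz around -40 mV: activation in the
  # depolarizing phase outweighs deactivation in the hyperpolarizing phase
  cmd <- build_sinusoid_vc(-40, 15, 0.5, n_cycles = 3, pre_ms = 2000,
                           dt = 0.05)
  sim <- run_voltage_clamp(cell_kcnq(), cmd)
  mk <- sinusoid_metrics(sim$response, baseline_window_ms = c(1000, 1999),
                         stim_onset_ms = 2000, freq_Hz = 0.5)
  expect_gt(mk$outward_amp_pA, mk$inward_amp_pA)
})

test_that("exponential fits recover tau and the 10-90% relation", {
  dt <- 0.5
  t <- (0:1999) * dt
  y <- 5 + 3 * exp(-t / 120)
  fit <- fit_exponential(y, dt = dt)
  expect_equal(fit$tau_ms, 120, tolerance = 1e-3)
  expect_equal(fit$amplitude, 3, tolerance = 1e-3)
  expect_equal(fit$offset, 5, tolerance = 1e-3)
  expect_equal(rise_time_10_90(120), 120 * log(9))
  # rising (negative-amplitude) segments fit equally well
  y2 <- 10 - 4 * exp(-t / 60)
  fit2 <- fit_exponential(y2, dt = dt)
  expect_equal(fit2$tau_ms, 60, tolerance = 1e-3)
})

test_that("Boltzmann fits recover midpoint, slope and translate exactly", {
  V <- seq(-70, 10, by = 10)
  G <- 12 / (1 + exp((-30 - V) / 8))
  fit <- fit_boltzmann(V, G)
  expect_equal(fit$V_half_mV, -30, tolerance = 1e-5)
  expect_equal(fit$k_mV, 8, tolerance = 1e-5)
  expect_equal(fit$G_max, 12, tolerance = 1e-5)
  # translation equivariance
  G2 <- 12 / (1 + exp((-45 - V) / 8))
  fit2 <- fit_boltzmann(V, G2)
  expect_equal(fit2$V_half_mV - fit$V_half_mV, -15, tolerance = 1e-4)
  # relative mode fixes G_max at 1
  fr <- fit_boltzmann(V, G / 12, relative = TRUE)
  expect_equal(fr$G_max, 1)
  expect_equal(fr$V_half_mV, -30, tolerance = 1e-5)
  expect_error(fit_boltzmann(V[1:3], G[1:3]), "at least 4")
  # non-spanning data are flagged low-confidence
  Vlow <- seq(-80, -55, by = 5)
  flagged <- fit_boltzmann(Vlow, 12 / (1 + exp((-30 - Vlow) / 8)))
  expect_true(flagged$low_confidence)
})
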