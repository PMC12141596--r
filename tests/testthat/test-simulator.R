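test_that("voltage-clamp steady state matches the analytic fixed point", {
  set.seed(42)
  area <- surface_area(cell_geometry()) * 1e-8
  for (i in 1:20) {
    p <- random_gating()
    ch <- channel_model(0.001, p, label = "rand")
    cell <- cell_model(channels = list(ch))
    V <- runif(1, -80, -10)
    hold_ms <- 20 * gate_time_constant(V, p)
    cmd <- ephys_trace(rep(V, round(hold_ms / 0.05)), 0.05, "voltage")
    sim <- run_voltage_clamp(cell, cmd)
    g_inf <- steady_conductance_density(V, ch) * area * 1e9
    i_inf <- g_inf * (V - cell$E_K)
    expect_equal(tail(sim$response$values, 1), i_inf,
                 tolerance = 1e-3)
  }
})

test_that("step currents jump instantaneously without inactivation and are
           cancelled by rapid inactivation", {
  dt <- 0.01
  cmd <- build_voltage_steps(-30, -20, pre_ms = 2000, step_ms = 2000,
                             post_ms = 100, dt = dt)[[1]]
  i_on <- round(2000 / dt) + 1L

  for (case in c("plain", "inactivating")) {
    cell <- if (case == "plain") cell_kcnq() else cell_kcnqi()
    sim <- run_voltage_clamp(cell, cmd)
    ipre <- mean(sim$response$values[(i_on - 1000):(i_on - 1)])
    jump_inst <- sim$conductance[i_on - 1L] * 10    # g_pre * dV, pA
    # instantaneous Ohmic discontinuity is present in both models
    expect_equal(sim$response$values[i_on] - ipre, jump_inst,
                 tolerance = 0.03)
    # 10 ms later the plain model still carries the step current, while
    # rapid inactivation has cancelled it (exponential change from baseline)
    dev10 <- sim$response$values[i_on + round(10 / dt)] - ipre
    if (case == "plain") expect_gt(dev10 / jump_inst, 0.8)
    else expect_lt(dev10 / jump_inst, 0.1)
  }
})

test_that("current clamp reproduces passive RC behaviour", {
  cell <- cell_passive()
  # rest: no injection, V settles to e_pas from any start, monotonically
  for (v0 in c(-100, -20)) {
    sim <- run_current_clamp(cell, ephys_trace(rep(0, 1e5), 0.05, "current"),
                             v0 = v0)
    expect_equal(tail(sim$response$values, 1), cell$e_pas, tolerance = 1e-6)
    dv <- diff(sim$response$values)
    expect_true(all(dv >= -1e-12) || all(dv <= 1e-12))
  }
  # small step: exponential charging with tau = cm/g_pas = R*C
  dt <- 0.05
  inj <- ephys_trace(c(rep(0, 1000), rep(10, round(3000 / dt))), dt,
                     "current")
  sim <- run_current_clamp(cell, inj, v0 = -60)
  seg <- sim$response$values[1001:length(inj$values)]
  fit <- fit_exponential(seg, dt = dt)
  tau_theory <- cell$cm / cell$g_pas * 1e-3       # ms
  expect_equal(fit$tau_ms, tau_theory, tolerance = 2e-3)
  expect_equal(fit$offset - (-60), 10 * input_resistance(cell) * 1e-3,
               tolerance = 1e-3)
})

test_that("IV families count sweeps and order plateau currents correctly", {
  ivq <- run_iv_family(cell_kcnq(), dt = 0.05)
  ivi <- run_iv_family(cell_kcnqi(), dt = 0.05)
  expect_equal(nrow(ivq), 7)                       # -70..-10 by 10
  expect_equal(ivq$V_mV, seq(-70, -10, by = 10))
  # inactivation can only reduce the plateau (h_inf <= 1)
  expect_true(all(ivi$I_plateau_pA <= ivq$I_plateau_pA + 1e-9))
  # far below the activation range the conductance is a tiny fraction of gmax
  sub <- run_iv_family(cell_kcnq(), holding_mV = -120,
                       step_levels_mV = -110, step_ms = 2000, dt = 0.05)
  gmax_tot <- 0.001 * surface_area(cell_geometry()) * 1e-8 * 1e9
  expect_lt(sub$g_plateau_nS / gmax_tot, 0.01)
})

test_that("halving dt leaves simulated responses unchanged to <0.5%", {
  # voltage-clamp step scenario: sample-wise comparison
  cellq <- cell_kcnq()
  for (dt in c(0.02)) {
    cmd1 <- build_voltage_steps(-30, -20, pre_ms = 500, step_ms = 500,
                                post_ms = 100, dt = dt)[[1]]
    cmd2 <- build_voltage_steps(-30, -20, pre_ms = 500, step_ms = 500,
                                post_ms = 100, dt = dt / 2)[[1]]
    s1 <- run_voltage_clamp(cellq, cmd1)
    s2 <- run_voltage_clamp(cellq, cmd2)
    i2 <- s2$response$values[seq(1, length(cmd2$values), by = 2)]
    rng <- diff(range(s1$response$values))
    expect_lt(max(abs(s1$response$values - i2)) / rng, 0.005)
  }
  # current-clamp chirp scenario (short sweep), sample-wise on the voltage
  spec <- chirp_spec(50, 0, 40, 5)
  z1 <- zap_response(cellq, -40, spec, dt = 0.02, settle_ms = 500,
                     tail_ms = 200)
  z2 <- zap_response(cellq, -40, spec, dt = 0.01, settle_ms = 500,
                     tail_ms = 200)
  v2 <- z2$V$values[seq(1, length(z2$V$values), by = 2)]
  rng <- diff(range(z1$V$values))
  expect_lt(max(abs(z1$V$values - v2)) / rng, 0.005)
})
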