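test_that("steady state is a Boltzmann with midpoint, floor and saturation", {
  p <- gating_params(theta = -61, k = 19.5, tau0 = 6.7, tau1 = 100,
                     phi = -61, sigma0 = 35, sigma1 = -25)
  expect_equal(gate_steady_state(-61, p), 0.5)

  ph <- gating_params(theta = -25, k = -6, tau0 = 1.5, tau1 = 8, phi = -25,
                      sigma0 = 15, sigma1 = -15, floor = 0.38)
  expect_equal(gate_steady_state(-25, ph), 0.38 + (1 - 0.38) / 2)
  # inactivation gate saturates to its floor 20 slope-widths above midpoint
  expect_lt(abs(gate_steady_state(-25 + 20 * 6, ph) - 0.38), 1e-4)
  expect_error(gate_steady_state(NaN, p), "finite")
})

test_that("time constant curve hits its closed-form landmarks", {
  p <- gating_params(theta = -61, k = 19.5, tau0 = 6.7, tau1 = 100,
                     phi = -61, sigma0 = 35, sigma1 = -25)
  expect_equal(gate_time_constant(-61, p), 6.7 + (100 - 6.7) / 2)
  # degenerate flat curve
  pf <- gating_params(theta = -61, k = 19.5, tau0 = 20, tau1 = 20,
                      phi = -61, sigma0 = 35, sigma1 = -25)
  expect_equal(gate_time_constant(seq(-120, 40, by = 5), pf),
               rep(20, 33))
  # one exponential diverges far from phi, so tau returns to tau0
  expect_lt(abs(gate_time_constant(-61 + 400, p) - 6.7), 5e-3)
  expect_lt(abs(gate_time_constant(-61 - 400, p) - 6.7), 5e-3)
})

test_that("gate_update is the exact relaxation and composes over steps", {
  p <- gating_params(theta = -61, k = 19.5, tau0 = 6.7, tau1 = 100,
                     phi = -61, sigma0 = 35, sigma1 = -25)
  expect_identical(gate_update(0.3, -40, 0, p), 0.3)
  tau <- gate_time_constant(-40, p)
  expect_lt(abs(gate_update(0.1, -40, 100 * tau, p) -
                gate_steady_state(-40, p)), 1e-6)
  expect_error(gate_update(0.3, -40, -1, p), "non-negative")

  # composition: two half-steps equal one full step at fixed V
  set.seed(11)
  for (i in 1:20) {
    V <- runif(1, -90, 0); x <- runif(1); d <- runif(1, 0.1, 50)
    expect_equal(gate_update(gate_update(x, V, d / 2, p), V, d / 2, p),
                 gate_update(x, V, d, p), tolerance = 1e-12)
  }
})

test_that("piecewise-constant trajectory matches a dense fine-step reference", {
  # oracle: the same trajectory integrated at dt/100; the coarse update is
  # exact for frozen V, so both must agree wherever V is piecewise constant
  p <- gating_params(theta = -61, k = 19.5, tau0 = 6.7, tau1 = 100,
                     phi = -61, sigma0 = 35, sigma1 = -25)
  set.seed(7)
  V_levels <- runif(8, -90, -10)
  dt <- 1
  x_coarse <- gate_steady_state(V_levels[1], p)
  x_fine <- x_coarse
  for (lev in V_levels) {
    for (k in 1:50) x_coarse <- gate_update(x_coarse, lev, dt, p)
    for (k in 1:5000) x_fine <- gate_update(x_fine, lev, dt / 100, p)
  }
  expect_lt(abs(x_coarse - x_fine), 1e-6)
})

test_that("gates stay bounded and monotone in voltage", {
  set.seed(21)
  vgrid <- seq(-120, 40, length.out = 1000)
  for (rep in 1:5) {
    p <- random_gating()
    ss <- gate_steady_state(vgrid, p)
    expect_true(all(diff(ss) > 0))          # k > 0: increasing
    expect_true(all(ss >= p$floor - 1e-12 & ss <= 1 + 1e-12))
    # arbitrary update sequence stays within [floor, 1]
    x <- runif(1, p$floor, 1)
    for (i in 1:200) {
      x <- gate_update(x, runif(1, -120, 40), runif(1, 0, 20), p)
      expect_true(x >= p$floor - 1e-12 && x <= 1 + 1e-12)
    }
  }
  pdec <- gating_params(theta = -40, k = -8, tau0 = 1, tau1 = 10,
                        phi = -40, sigma0 = 15, sigma1 = -15, floor = 0.1)
  expect_true(all(diff(gate_steady_state(vgrid, pdec)) < 0))  # k < 0
})

test_that("conductance and current follow the product and Ohmic forms", {
  m4 <- gating_params(theta = -61, k = 19.5, tau0 = 6.7, tau1 = 100,
                      phi = -61, sigma0 = 35, sigma1 = -25, exponent = 4)
  ch <- channel_model(0.001, m4, label = "kcnq")
  area <- 7.539822e-5                        # cm^2
  expect_equal(channel_conductance(1, ch, area), 0.001 * area * 1e9)
  expect_equal(channel_conductance(0, ch, area), 0)
  expect_equal(channel_conductance(0.5, ch, area),
               0.001 * area * 1e9 * 0.0625)
  expect_error(channel_conductance(0.5, ch, -1), "positive")

  expect_equal(channel_current(1, -97.5, -97.5), 0)
  expect_equal(channel_current(1, -39.5, -97.5), 58)
  expect_lt(channel_current(2, -110, -97.5), 0)   # inward below E_K
  expect_error(channel_current(-1, 0, -97.5), "non-negative")

  # steady conductance density never exceeds gmax
  v <- seq(-120, 60, by = 1)
  expect_true(all(steady_conductance_density(v, ch) <= ch$gmax_density))
  chi <- kcnq_inactivation_model()
  expect_true(all(steady_conductance_density(v, chi) <= chi$gmax_density))
})

test_that("parameter files round-trip losslessly", {
  models <- list(a = kcnq_model(), b = kcnq_inactivation_model())
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_channel_params(models, tmp)
  back <- read_channel_params(tmp)
  expect_equal(back$a$activation$theta, models$a$activation$theta)
  expect_equal(back$b$inactivation$floor, models$b$inactivation$floor)
  expect_equal(back$b$inactivation$tau1, models$b$inactivation$tau1)
  expect_equal(back$a$gmax_density, models$a$gmax_density)
})

test_that("invalid gating parameters are rejected at construction", {
  expect_error(gating_params(-61, 19.5, tau0 = -1, tau1 = 100, phi = -61,
                             sigma0 = 35, sigma1 = -25), "positive")
  expect_error(gating_params(-61, 19.5, tau0 = 5, tau1 = 100, phi = -61,
                             sigma0 = 35, sigma1 = -25, floor = 1), "floor")
  # sigma pair that drives the denominator negative -> tau <= 0 somewhere
  expect_error(gating_params(-61, 19.5, tau0 = 1, tau1 = -50, phi = -61,
                             sigma0 = 35, sigma1 = -25), "positive")
})
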