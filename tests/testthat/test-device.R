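Q_E <- 1.602176634e-19

test_that("transfer curve has the compact-model limits", {
  dev <- device_params()
  sol <- solution_spec(c(Ca = 1e-3))
  mem <- ism_library()$Ca
  # no drain bias, no current
  iv0 <- simulate_iv(dev, mem, sol, v_ds = 0)
  expect_true(all(iv0$i_ds_A == 0))
  # at the reference concentration the minimum sits at the doped Dirac
  # voltage (within one grid step)
  iv <- simulate_iv(dev, mem, sol)
  vmin <- iv$v_gs_V[which.min(iv$i_ds_A)]
  expect_lt(abs(vmin - (dev$V_dirac0 + mem$doping_offset_V)), 0.011)
  # closed form at the Dirac point with no contact resistance
  dev0 <- device_params(R_c = 0, V_dirac0 = 0.2)
  iv2 <- simulate_iv(dev0, NULL, sol, v_gs = c(0.1, 0.2, 0.3), v_ds = 0.3)
  expect_equal(iv2$i_ds_A[2],
               0.3 * (dev0$W / dev0$L) * Q_E * dev0$mu * dev0$n0,
               tolerance = 1e-12)
})

test_that("concentration change is a pure translation of the I-V curve", {
  dev <- device_params(sens_scale = 1)
  mem <- membrane_spec("K", 1)
  grid <- seq(-0.6, 0.9, by = 0.01)
  shift <- nernst_slope(1)  # one decade, z = 1, sens_scale = 1
  iv_hi <- simulate_iv(dev, mem, solution_spec(c(K = 1e-2)), 1e-3,
                       v_gs = grid)
  iv_lo_shifted <- simulate_iv(dev, mem, solution_spec(c(K = 1e-3)), 1e-3,
                               v_gs = grid + shift)
  expect_lt(max(abs(iv_hi$i_ds_A / iv_lo_shifted$i_ds_A - 1)), 1e-12)
})

test_that("invalid sweep grids are rejected", {
  dev <- device_params()
  sol <- solution_spec(c(K = 1e-3))
  expect_error(simulate_iv(dev, NULL, sol, v_gs = c(0, 0.1)))
  expect_error(simulate_iv(dev, NULL, sol, v_gs = c(0, 0.1, 0.05)))
  expect_error(device_params(mu = -1))
  expect_error(device_params(R_c = -1))
})

test_that("transient relaxes exponentially toward the steady state", {
  dev <- device_params()
  mem <- ism_library()$Ca
  sols <- list(solution_spec(c(Ca = 1e-3)), solution_spec(c(Ca = 1e-2)))
  # instantaneous limit: piecewise constant at the steady-state currents
  tr0 <- simulate_transient(dev, mem, sols, dwell_s = 2, dt = 0.5,
                            tau_s = 0)
  ss <- vapply(sols, function(s) {
    simulate_iv(dev, mem, s, v_gs = c(-0.11, -0.1, -0.09))$i_ds_A[2]
  }, numeric(1))
  expect_equal(unique(tr0$i_ds_A[tr0$solution == tr0$solution[1]]), ss[1])
  expect_equal(unique(tr0$i_ds_A[tr0$solution != tr0$solution[1]]), ss[2])
  # steady state equals the I-V value exactly without noise
  tr <- simulate_transient(dev, mem, sols, dwell_s = c(5, 60), dt = 0.01)
  expect_equal(tr$i_ds_A[nrow(tr)], ss[2], tolerance = 1e-8)
  # 90% response time equals tau * ln(10); doubling tau doubles it
  t1 <- response_time(tr$time_s, tr$i_ds_A, step_time = 5)
  expect_equal(t1, mem$tau_s * log(10), tolerance = 0.01)
  tr2 <- simulate_transient(dev, mem, sols, dwell_s = c(5, 60), dt = 0.01,
                            tau_s = 2 * mem$tau_s)
  t2 <- response_time(tr2$time_s, tr2$i_ds_A, step_time = 5)
  expect_equal(t2 / t1, 2, tolerance = 0.01)
  # hole branch: higher cation concentration lowers the conductance
  expect_lt(ss[2], ss[1])
  expect_error(simulate_transient(dev, mem, list(), dwell_s = 1))
})

test_that("population-mean response times match the characterized ISMs", {
  pop <- population_model()
  for (spec in list(c("K", 7.4), c("Na", 5.9), c("Ca", 5.1))) {
    chip <- sample_chip(chip_layout(16, 16, spec[1]), pop,
                        chip_id = "t", seed = 5L)
    t90 <- chip$tau_s[chip$functional] * log(10)
    expect_equal(mean(t90), as.numeric(spec[2]), tolerance = 0.1)
  }
})
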