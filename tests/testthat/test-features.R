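test_that("working-device screen rejects dead and saturated curves", {
  v <- seq(-0.6, 0.9, by = 0.01)
  dead <- tibble::tibble(chip_id = "c", row = 1L, col = 1L, ism = "Ca",
                         solution = "s", v_gs_V = v, i_ds_A = 0)
  expect_false(filter_working(dead)$working)
  flat <- dead; flat$i_ds_A <- 1e-5  # no modulation
  expect_false(filter_working(flat)$working)
  iv <- simulate_iv(device_params(), ism_library()$Ca,
                    solution_spec(c(Ca = 1e-3)))
  good <- tibble::tibble(chip_id = "c", row = 1L, col = 1L, ism = "Ca",
                         solution = "s", v_gs_V = iv$v_gs_V,
                         i_ds_A = iv$i_ds_A)
  expect_true(filter_working(good)$working)
})

test_that("default population passes the yield screen above 80%", {
  chip <- ca_chip()
  m <- run_panel(chip, list(solution_spec(c(Ca = 1e-3))), seed = 12L)
  wk <- filter_working(m)
  expect_gt(chip_yield(wk, nrow(chip)), 0.80)
})

test_that("Dirac extraction is exact on a parabola and near-exact on curves", {
  v <- seq(-0.2, 0.5, by = 0.01)
  i <- 1e-6 * (1 + 40 * (v - 0.15)^2)
  expect_equal(dirac_point(v, i), 0.15, tolerance = 1e-10)
  # dense-grid brute-force oracle on noiseless simulated devices
  withr::with_seed(31L, {
    for (k in 1:8) {
      dev <- device_params(V_dirac0 = runif(1, 0.05, 0.3),
                           mu = rlnorm(1, log(0.1), 0.3),
                           R_c = rlnorm(1, log(1000), 0.3),
                           n0 = rlnorm(1, log(5e15), 0.3))
      iv <- simulate_iv(dev, NULL, solution_spec(c(Ca = 1e-3)))
      dense <- simulate_iv(dev, NULL, solution_spec(c(Ca = 1e-3)),
                           v_gs = seq(-0.6, 0.9, by = 1e-4))
      oracle <- dense$v_gs_V[which.min(dense$i_ds_A)]
      expect_lt(abs(dirac_point(iv$v_gs_V, iv$i_ds_A) - oracle), 0.005)
    }
  })
  # minimum on the sweep edge is an error
  vv <- seq(0, 0.5, by = 0.01)
  expect_error(dirac_point(vv, vv + 1), class = "ionarray_edge_minimum")
})

test_that("extracted features have the expected geometry", {
  f <- tiny_fixture()$features
  expect_true(all(f$gm_max_A_per_V > 0))
  expect_true(all(f$gm_min_A_per_V < 0))
  expect_true(all(f$v_dirac_V > -0.6 & f$v_dirac_V < 0.9))
  expect_true(all(c("i_at_m0p1V_A", "i_at_0p6V_A", "asymmetry") %in%
                    names(f)))
  expect_true(all(f$i_min_A <= f$i_at_0p6V_A))
})

test_that("sensitivity recovers constructed and simulated slopes", {
  # points exactly on a -54.7 mV/decade line
  concs <- 10^(-5:-1)
  df <- tibble::tibble(row = 1L, col = 1L, conc_mol_per_L = concs,
                       v_dirac_V = 0.4 - 0.0547 * log10(concs / 1e-3))
  s <- sensitivity(df)
  expect_equal(s$slope, -54.7, tolerance = 1e-9)
  # two points: exact two-point slope
  df2 <- tibble::tibble(row = 1L, col = 1L, conc_mol_per_L = c(1e-3, 1e-2),
                        v_dirac_V = c(0.3, 0.24))
  expect_equal(sensitivity(df2)$slope, -60, tolerance = 1e-9)
  # noiseless ideal z=1 chip with sens_scale == 1: the Nernst slope
  chip <- ideal_k_chip()
  sols <- lapply(10^(-5:-1), function(ci) solution_spec(c(K = ci)))
  m <- run_panel(chip, sols, noise_rel = 0, seed = 32L)
  f <- extract_features(m)
  fd <- dplyr::left_join(f, dplyr::select(solutions_table(sols),
                                          "solution", "conc_mol_per_L"),
                         by = "solution")
  expect_equal(sensitivity(fd)$slope, -59.16, tolerance = 0.5 / 59)
  expect_error(sensitivity(df[1, ]))
})

test_that("array sensitivity recovers the generative slope within 2 s.e.", {
  pop <- population_model(yield_p = 1)
  sols <- ca_solutions()
  target <- unname(pop$sens_mean["Ca"]) * -1000 * nernst_slope(2)
  slopes <- vapply(1:25, function(r) {
    chip <- sample_chip(chip_layout(5, 5, "Ca"), pop, chip_id = "r",
                        seed = 500L + r)
    m <- run_panel(chip, sols, seed = 600L + r)
    f <- extract_features(m)
    fd <- dplyr::left_join(f, dplyr::select(solutions_table(sols),
                                            "solution", "conc_mol_per_L"),
                           by = "solution")
    sensitivity(fd)$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - target), 2 * se + 0.05)
})

test_that("array-mean sensitivity precision improves with device count", {
  pop <- population_model(yield_p = 1)
  sols <- ca_solutions(10^c(-4, -3, -2))
  sd_for <- function(n_side, seeds) {
    vapply(seeds, function(r) {
      chip <- sample_chip(chip_layout(n_side, n_side, "Ca"), pop,
                          chip_id = "r", seed = 700L + r)
      m <- run_panel(chip, sols, seed = 800L + r)
      f <- extract_features(m)
      fd <- dplyr::left_join(f, dplyr::select(solutions_table(sols),
                                              "solution", "conc_mol_per_L"),
                             by = "solution")
      sensitivity(fd)$slope
    }, numeric(1))
  }
  s_small <- sd(sd_for(3, 1:20))
  s_large <- sd(sd_for(6, 1:20))
  # 4x the devices: s.e. should shrink by about 2 (allow wide MC slack)
  expect_gt(s_small / s_large, 1.3)
})

test_that("reversibility metric matches its formula and degenerate cases", {
  mk <- function(sf, sb) {
    concs <- 10^(-4:-1)
    tibble::tibble(
      row = 1L, col = 1L,
      direction = rep(c("forward", "backward"), each = 4),
      conc_mol_per_L = rep(concs, 2),
      response_pct = c(sf * log10(concs), sb * log10(concs)))
  }
  expect_equal(reversibility(mk(1, 1))$array_pct, 0)
  expect_equal(reversibility(mk(1, 0.9))$array_pct, 100 * 0.1 / 0.95,
               tolerance = 1e-9)
  expect_equal(round(reversibility(mk(1, 0.9))$array_pct, 3), 10.526)
  expect_error(reversibility(mk(0, 0)), "zero mean slope")
  one_dir <- mk(1, 1)[1:4, ]
  expect_error(reversibility(one_dir), "forward and backward")
})

test_that("response time handles steps, interpolation and errors", {
  t <- seq(0, 40, by = 0.01)
  i0 <- 1e-5; amp <- -4e-6; tau <- 3.213
  i <- i0 + amp * (1 - exp(-pmax(t - 5, 0) / tau))
  expect_equal(response_time(t, i, step_time = 5), tau * log(10),
               tolerance = 0.01)
  # instantaneous step: the first post-step sample already crossed
  ti <- c(0, 1, 2, 3, 4, 5, 6, 7)
  ii <- c(1, 1, 1, 1, 1, 2, 2, 2)
  expect_equal(response_time(ti, ii, step_time = 5), 0)
  expect_error(response_time(t, rep(1, length(t)), step_time = 5))
  # truncated trace with a known asymptote: threshold never reached
  expect_error(response_time(t[t < 6], i[t < 6], step_time = 5,
                             i_final = i0 + amp),
               "threshold")
})
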