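cal_fixture <- function() memo("cal_meas", function() {
  chip <- ca_chip()
  list(chip = chip,
       cal = run_panel(chip, list(solution_spec(c(Ca = 1e-3))),
                       seed = 41L))
})

test_that("a slice matches itself exactly (R^2 = 1, delta_v = 0)", {
  cal <- cal_fixture()$cal
  sl <- current_slice(cal, "Ca_1mM", v_gs = 0.2)
  for (obj in c("lsq", "correlation")) {
    m <- match_profile(sl, cal, smooth_pts = 1, objective = obj)
    expect_equal(m$v_star, 0.2, tolerance = 1e-12)
    expect_equal(m$delta_v, 0, tolerance = 1e-12)
    expect_equal(m$r2_max, 1, tolerance = 1e-12)
    expect_equal(m$profile$r2[which.min(abs(m$profile$v_gs_V - 0.2))], 1,
                 tolerance = 1e-12)
  }
})

test_that("R^2 profile is invariant to affine rescaling of the test slice", {
  cal <- cal_fixture()$cal
  sl <- current_slice(cal, "Ca_1mM", v_gs = 0.1)
  m1 <- match_profile(sl, cal, objective = "correlation")
  sl2 <- sl
  sl2$i_ds_A <- 3.7 * sl2$i_ds_A + 1e-6
  m2 <- match_profile(sl2, cal, objective = "correlation")
  expect_equal(m1$profile$r2, m2$profile$r2, tolerance = 1e-9)
  expect_equal(m1$v_star, m2$v_star, tolerance = 1e-12)
  # v_star attains the R^2 maximum in correlation mode
  expect_equal(m1$profile$v_gs_V[which.max(m1$profile$r2)], m1$v_star,
               tolerance = 0.011)
})

test_that("noiseless translation is recovered within half a grid step", {
  chip <- ideal_k_chip()
  cal <- run_panel(chip, list(solution_spec(c(K = 1e-3))), noise_rel = 0,
                   seed = 42L)
  test_m <- run_panel(chip, list(solution_spec(c(K = 1e-2))),
                      noise_rel = 0, seed = 43L)
  sl <- current_slice(test_m, "K_10mM", v_gs = 0)
  m <- match_profile(sl, cal)
  expect_equal(m$delta_v, nernst_slope(1), tolerance = 0.005 / 0.059)
  # R^2 profile is unimodal around the optimum on noiseless data
  r2 <- m$profile$r2
  j <- which.max(r2)
  win <- (j - 8):(j + 8)
  expect_true(all(diff(r2[win[win <= j]]) > 0))
  expect_true(all(diff(r2[win[win >= j]]) < 0))
})

test_that("match_profile validates device overlap and degenerate slices", {
  cal <- cal_fixture()$cal
  sl <- current_slice(cal, "Ca_1mM", v_gs = 0)
  expect_error(match_profile(sl[1:5, ], cal), "devices")
  sl0 <- sl; sl0$i_ds_A <- rep(1e-6, nrow(sl0))
  expect_error(match_profile(sl0, cal, objective = "correlation"),
               "zero variance")
  two_sol <- dplyr::bind_rows(cal, dplyr::mutate(cal, solution = "other"))
  expect_error(match_profile(sl, two_sol), "single")
})

test_that("voltage shifts convert to concentrations by the Nernst relation", {
  expect_equal(estimate_concentration(0, 1e-3, -59.16), 1e-3)
  expect_equal(estimate_concentration(0.05916, 1e-3, -59.16), 1e-2,
               tolerance = 1e-9)
  expect_equal(estimate_concentration(-0.02958, 1e-3, -29.58), 1e-4,
               tolerance = 1e-9)
  expect_error(estimate_concentration(0.01, 1e-3, 0), "non-zero")
})

test_that("noiseless chips recover concentrations almost exactly", {
  ca <- calibration_accuracy(ca_chip(), noise_rel = 0, seed = 44L)
  expect_equal(ca$slope, 1, tolerance = 0.02)
  expect_gt(ca$r_squared, 0.9995)
  expect_true(all(diff(ca$estimates$c_est_mol_per_L) > 0))
})

test_that("round-trip recovery stays within 15% on default-noise chips", {
  ca <- calibration_accuracy(ca_chip(), seed = 45L)
  rel_err <- abs(ca$estimates$c_est_mol_per_L /
                   ca$estimates$conc_mol_per_L - 1)
  expect_lt(max(rel_err), 0.15)
  kchip <- sample_chip(chip_layout(16, 16, "K"), population_model(),
                       chip_id = "k", seed = 46L)
  cak <- calibration_accuracy(kchip, ism = "K", seed = 47L)
  rel_err_k <- abs(cak$estimates$c_est_mol_per_L /
                     cak$estimates$conc_mol_per_L - 1)
  expect_lt(max(rel_err_k), 0.15)
})

test_that("redundancy CI is zero for a zero-variance population", {
  vals <- matrix(rep(simulate_iv(device_params(), ism_library()$Ca,
                                 solution_spec(c(Ca = 1e-3)))$i_ds_A,
                     each = 50), nrow = 50)
  tst <- simulate_iv(device_params(), ism_library()$Ca,
                     solution_spec(c(Ca = 1e-2)))
  vals <- cbind(vals, rep(tst$i_ds_A[61], 50))  # V_GS = 0 slice
  popn <- structure(list(
    values = vals,
    columns = tibble::tibble(
      solution = c(rep("cal", 151), "test"),
      v_gs_V = c(seq(-0.6, 0.9, by = 0.01), 0)),
    u = rep(0.5, 50), n_source = 50, v_ds_V = 0.3),
    class = "ion_population")
  red <- redundancy_ci(popn, sample_sizes = c(5, 20), n_repeats = 50,
                       true_conc = 1e-2, c_ref = 1e-3,
                       slope_mV_per_decade = -30.1, seed = 48L)
  expect_equal(red$half_width_pct, c(0, 0))
})

test_that("confidence half-width shrinks with array size", {
  chip <- ca_chip()
  cal <- cal_fixture()$cal
  test_m <- run_panel(chip, list(solution_spec(c(Ca = 1e-2))),
                      noise_rel = 0.01 / 5, seed = 49L)
  test_sl <- test_m[test_m$v_gs_V == 0, ]
  popn <- ecdf_synthesize(dplyr::bind_rows(cal, test_sl), 10000,
                          seed = 50L)
  hw <- lapply(1:4, function(s) {
    red <- redundancy_ci(popn, sample_sizes = c(5, 15, 60, 150),
                         n_repeats = 120, true_conc = 1e-2, c_ref = 1e-3,
                         slope_mV_per_decade = -30.1, seed = 60L + s)
    red$half_width_pct
  })
  pooled_n <- rep(c(5, 15, 60, 150), 4)
  pooled_hw <- unlist(hw)
  ct <- suppressWarnings(
    cor.test(pooled_n, pooled_hw, method = "spearman",
             alternative = "less"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
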