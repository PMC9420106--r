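# Frozen oracle values computed from ln(10) * R * T / (z F) with
# R = 8.314462618 J/(mol K), F = 96485.33212 C/mol, T = 298.15 K.
NERNST_Z1 <- 0.0591593476
NERNST_Z2 <- 0.0295796738

test_that("Nernst slope matches the analytic value at both valences", {
  expect_equal(nernst_slope(1), NERNST_Z1, tolerance = 1e-6)
  expect_equal(nernst_slope(2), NERNST_Z2, tolerance = 1e-6)
  expect_equal(nernst_slope(2), nernst_slope(1) / 2, tolerance = 1e-12)
  # slope scales linearly with temperature
  expect_equal(nernst_slope(1, 310), nernst_slope(1) * 310 / 298.15,
               tolerance = 1e-12)
})

test_that("membrane potential follows the Nernst equation", {
  mem1 <- membrane_spec("K", 1)
  mem2 <- membrane_spec("Ca", 2)
  expect_equal(membrane_potential(mem1, solution_spec(c(K = 1e-3)), 1e-3), 0)
  expect_equal(membrane_potential(mem1, solution_spec(c(K = 1e-2)), 1e-3),
               NERNST_Z1, tolerance = 1e-6)
  expect_equal(membrane_potential(mem2, solution_spec(c(Ca = 1e-2)), 1e-3),
               NERNST_Z2, tolerance = 1e-6)
  # linear in log10(c) with the Nernst slope
  concs <- 10^seq(-5, -1)
  v <- vapply(concs, function(ci)
    membrane_potential(mem1, solution_spec(c(K = ci)), 1e-3), numeric(1))
  slopes <- diff(v) / diff(log10(concs))
  expect_equal(slopes, rep(nernst_slope(1), 4), tolerance = 1e-12)
})

test_that("Nikolsky-Eisenman cross-terms raise the effective activity", {
  mem <- membrane_spec("K", 1, selectivity = c(Na = 0.01))
  pure <- membrane_potential(mem, solution_spec(c(K = 1e-3)), 1e-3)
  mixed <- membrane_potential(mem,
    solution_spec(c(K = 1e-3, Na = 1e-1)), 1e-3)
  expect_gt(mixed, pure)
  # K_ij * c_j^(z_i/z_j) with z_i = z_j = 1: a_eff = c_K + 0.01 * c_Na
  expect_equal(mixed, nernst_slope(1) * log10((1e-3 + 0.01 * 1e-1) / 1e-3),
               tolerance = 1e-12)
})

test_that("membrane potential rejects degenerate inputs", {
  mem <- membrane_spec("K", 1)
  expect_error(membrane_potential(mem, solution_spec(c(K = 1e-3)), 0))
  expect_error(membrane_potential(mem, solution_spec(c(Na = 1e-3)), 1e-3),
               "activity")
  expect_error(membrane_spec("K", 3))
  expect_error(membrane_spec("K", 1, selectivity = c(Na = -0.1)))
  expect_error(membrane_spec("K", 1, tau_s = 0))
})

test_that("stock membranes encode the study conditions", {
  lib <- ism_library()
  expect_named(lib, c("K", "Na", "Ca"))
  expect_equal(lib$Ca$z, 2L)
  # population-mean 90% response times: tau_s * ln(10)
  t90 <- vapply(lib, function(m) m$tau_s * log(10), numeric(1))
  expect_equal(unname(t90), c(7.4, 5.9, 5.1), tolerance = 1e-12)
  # K+ and Ca2+ membranes p-dope the channel far more than Na+
  expect_gt(lib$K$doping_offset_V, lib$Na$doping_offset_V)
  expect_gt(lib$Ca$doping_offset_V, lib$Na$doping_offset_V)
})

test_that("solution panels have the documented composition", {
  pure <- pure_solution_panel()
  expect_length(pure, 15)
  tbl <- solutions_table(pure)
  expect_setequal(unique(tbl$species), c("K", "Na", "Ca"))
  expect_setequal(unique(tbl$conc_mol_per_L), 10^(-5:-1))

  mix <- mixture_solution_panel(n = 30, seed = 7)
  expect_length(mix, 30)
  mt <- solutions_table(mix)
  wide <- tidyr::pivot_wider(mt, id_cols = "solution",
                             names_from = "species",
                             values_from = "conc_mol_per_L")
  expect_true(all(rowSums(wide[, c("K", "Na", "Ca")]) > 0))
  for (ion in c("K", "Na", "Ca"))
    expect_setequal(unique(wide[[ion]]), c(0, 10^(-4:-1)))
})

test_that("solution tables round-trip", {
  sols <- pure_solution_panel()[c(1, 7, 15)]
  back <- solutions_from_table(solutions_table(sols))
  expect_equal(lapply(back, unclass), lapply(sols, unclass))
})
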