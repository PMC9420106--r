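# Shared simulation fixtures, built once per test run and memoized.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# 16 x 16 Ca2+ ISM chip at the default population (the calibration /
# reversibility study chip).
ca_chip <- function() memo("ca_chip", function() {
  sample_chip(chip_layout(16, 16, "Ca"), population_model(),
              chip_id = "ca", seed = 101L)
})

ca_solutions <- function(concs = 10^(-5:-1)) {
  lapply(concs, function(ci) solution_spec(c(Ca = ci)))
}

# Integrated three-ISM chip with the full pure panel, measured noiselessly
# (used for separability / PCA / SHAP checks).
integrated_fixture <- function() memo("integrated", function() {
  chip <- sample_chip(chip_layout(16, 16, c("K", "Na", "Ca")),
                      population_model(), chip_id = "int", seed = 202L)
  solutions <- pure_solution_panel()
  measurement <- run_panel(chip, solutions, noise_rel = 0, seed = 203L)
  features <- extract_features(measurement)
  list(chip = chip, solutions = solutions, measurement = measurement,
       features = features)
})

# noisy integrated panel (default study conditions) for the
# device-subsampling experiments
noisy_integrated <- function() memo("noisy_integrated", function() {
  chip <- sample_chip(chip_layout(16, 16, c("K", "Na", "Ca")),
                      population_model(), chip_id = "nint", seed = 204L)
  solutions <- pure_solution_panel()
  measurement <- run_panel(chip, solutions, noise_rel = 0.01, seed = 205L)
  list(features = extract_features(measurement), solutions = solutions)
})

# tiny single-ISM fixture for fast unit tests
tiny_fixture <- function() memo("tiny", function() make_fixtures("tiny"))

# uniform monovalent chip (sens_scale == 1, no spread) for exact-shift
# checks
ideal_k_chip <- function() memo("ideal_k", function() {
  pop <- population_model(
    sens_mean = c(K = 1, Na = 1, Ca = 1, bare = 0),
    sens_sd = c(K = 1e-12, Na = 1e-12, Ca = 1e-12, bare = 1e-12),
    yield_p = 1)
  sample_chip(chip_layout(8, 8, "K"), pop, chip_id = "idealK",
              seed = 303L)
})

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x / y - 1)), tol)
}
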