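#' Read and write measurement, solution and feature tables
#'
#' Plain-CSV persistence for the long-format tables used throughout:
#' measurements (`chip_id,row,col,ism,solution,direction,v_ds_V,v_gs_V,i_ds_A`),
#' solution metadata (`solution,species,conc_mol_per_L,temperature_K`) and
#' feature tables. UTF-8, '.' decimal, header row mandatory; currents in
#' amperes, voltages in volts, concentrations in mol/L.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `write_*` return `x` invisibly; `read_*` return a tibble.
#' @name ion_io
NULL

#' @rdname ion_io
#' @export
write_measurement <- function(x, path) {
  need <- c("chip_id", "row", "col", "ism", "solution", "v_ds_V",
            "v_gs_V", "i_ds_A")
  stopifnot(all(need %in% names(x)))
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname ion_io
#' @export
read_measurement <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chip_id", "row", "col", "ism", "solution", "v_ds_V",
            "v_gs_V", "i_ds_A")
  missing <- setdiff(need, names(x))
  if (length(missing))
    abort(paste0("measurement file lacks column(s): ",
                 paste(missing, collapse = ", ")))
  x
}

#' @rdname ion_io
#' @export
write_solutions <- function(x, path) {
  if (!is.data.frame(x)) x <- solutions_table(x)
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname ion_io
#' @export
read_solutions <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("solution", "species", "conc_mol_per_L"), names(x))
  if (length(missing))
    abort(paste0("solution file lacks column(s): ",
                 paste(missing, collapse = ", ")))
  x
}

#' @rdname ion_io
#' @export
write_features <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname ion_io
#' @export
read_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Default run configuration
#'
#' Nested configuration for [run_pipeline()], serializable to/from YAML.
#' The `"default"` scale reproduces the full study conditions (16 x 16
#' chips, 15 pure solutions, 50,000-device synthetic population, 1000
#' redundancy repeats); `"tiny"` is a seconds-scale smoke configuration.
#'
#' @param scale `"default"` or `"tiny"`.
#' @param seed Master seed; every stage derives its own child seed.
#' @return Nested list of class `run_config`.
#' @export
run_config <- function(scale = c("default", "tiny"), seed = 1L) {
  scale <- match.arg(scale)
  cfg <- list(
    seed = as.integer(seed),
    scale = scale,
    layout = list(n_rows = 16L, n_cols = 16L, isms = c("K", "Na", "Ca")),
    population = list(yield_p = 0.84),
    panel = list(v_gs_from = -0.6, v_gs_to = 0.9, v_gs_by = 0.01,
                 v_ds = 0.3, noise_rel = 0.01, c_ref = 1e-3,
                 concentrations = 10^(-5:-1), hysteresis_V = 0.002),
    calibration = list(ism = "Ca", test_v_gs = 0, true_conc = 1e-2),
    redundancy = list(n_synthetic = 50000L, n_repeats = 1000L,
                      sample_sizes = c(5L, 25L, 100L, 215L)),
    ml = list(n_triplets = 200L, noise_frac = 0.05, n_repeats = 5L,
              trees = 100L, depth = 20L,
              tasks = c("ion_type", "conc_K", "conc_Na", "conc_Ca"))
  )
  if (scale == "tiny") {
    cfg$layout <- list(n_rows = 6L, n_cols = 6L, isms = c("K", "Na", "Ca"))
    cfg$panel$concentrations <- 10^c(-4, -3, -2)
    cfg$redundancy <- list(n_synthetic = 2000L, n_repeats = 100L,
                           sample_sizes = c(5L, 25L))
    cfg$ml <- modifyList(cfg$ml, list(n_triplets = 20L, n_repeats = 2L,
                                      tasks = "ion_type"))
  }
  structure(cfg, class = c("run_config", "list"))
}

required_config_keys <- function() {
  list(seed = NULL, scale = NULL,
       layout = c("n_rows", "n_cols", "isms"),
       population = c("yield_p"),
       panel = c("v_gs_from", "v_gs_to", "v_gs_by", "v_ds", "noise_rel",
                 "c_ref", "concentrations", "hysteresis_V"),
       calibration = c("ism", "test_v_gs", "true_conc"),
       redundancy = c("n_synthetic", "n_repeats", "sample_sizes"),
       ml = c("n_triplets", "noise_frac", "n_repeats", "trees", "depth",
              "tasks"))
}

#' Validate a run configuration
#'
#' Checks that every required key is present, erroring with the name of
#' the first missing key.
#'
#' @param config A configuration list.
#' @return The config, invisibly, with class `run_config`.
#' @export
validate_run_config <- function(config) {
  req <- required_config_keys()
  for (top in names(req)) {
    if (is.null(config[[top]]))
      abort(paste0("config is missing required key: '", top, "'."))
    for (sub in req[[top]])
      if (is.null(config[[top]][[sub]]))
        abort(paste0("config is missing required key: '", top, ".", sub, "'."))
  }
  class(config) <- c("run_config", "list")
  invisible(config)
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config Configuration to write.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

stage_log <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[%s] starting", name))
  out <- tryCatch(expr, error = function(e)
    abort(sprintf("[stage %s] %s", name, conditionMessage(e))))
  message(sprintf("[%s] done in %.1f s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full simulate-extract-calibrate-classify-redundancy pipeline
#'
#' Deterministic end-to-end run: simulates an integrated three-ISM chip and
#' a single-ISM calibration chip, measures the pure-solution panel (both
#' sweep directions), extracts features, runs the profile-matching
#' calibration accuracy experiment, the ECDF redundancy study, the
#' reversibility analysis and the classification tasks, and writes all
#' stage outputs plus a machine-readable `summary.json` into `out_dir`.
#' Logs stage timings to stderr.
#'
#' @param config A [run_config()] (validated on entry).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; defaults to `config$seed`.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config = run_config(), out_dir = "ionarray-run",
                         seed = NULL) {
  validate_run_config(config)
  seed <- as.integer(seed %||% config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$panel
  v_gs <- seq(p$v_gs_from, p$v_gs_to, by = p$v_gs_by)
  pop <- population_model(yield_p = config$population$yield_p)
  membranes <- ism_library()
  summary <- list(seed = seed, scale = config$scale)

  sim <- stage_log("simulate", {
    layout <- chip_layout(config$layout$n_rows, config$layout$n_cols,
                          config$layout$isms)
    chip <- sample_chip(layout, pop, membranes, chip_id = "integrated",
                        seed = child_seed(seed, 1))
    cal_layout <- chip_layout(config$layout$n_rows, config$layout$n_cols,
                              config$calibration$ism)
    cal_chip <- sample_chip(cal_layout, pop, membranes, chip_id = "cal",
                            seed = child_seed(seed, 2))
    solutions <- pure_solution_panel(config$layout$isms,
                                     p$concentrations)
    meas <- run_panel(chip, solutions, c_ref = p$c_ref, v_gs = v_gs,
                      v_ds = p$v_ds, direction = "both",
                      noise_rel = p$noise_rel,
                      hysteresis_V = p$hysteresis_V,
                      seed = child_seed(seed, 3))
    write_measurement(meas, file.path(out_dir, "measurements.csv"))
    write_solutions(solutions, file.path(out_dir, "solutions.csv"))
    list(chip = chip, cal_chip = cal_chip, solutions = solutions,
         meas = meas)
  })

  feats <- stage_log("extract", {
    f <- extract_features(sim$meas)
    write_features(f, file.path(out_dir, "features.csv"))
    f
  })
  summary$yield <- chip_yield(
    dplyr::distinct(feats, .data$row, .data$col, working = TRUE),
    nrow(sim$chip))

  calres <- stage_log("calibrate", {
    ca <- calibration_accuracy(
      sim$cal_chip, concentrations = p$concentrations, c_ref = p$c_ref,
      ism = config$calibration$ism,
      test_v_gs = config$calibration$test_v_gs, v_gs = v_gs,
      v_ds = p$v_ds, noise_rel = p$noise_rel, membranes = membranes,
      seed = child_seed(seed, 4))
    readr::write_csv(ca$estimates, file.path(out_dir, "calibration.csv"))
    ca
  })
  summary$calibration <- list(slope = calres$slope,
                              r_squared = calres$r_squared)

  redres <- stage_log("redundancy", {
    ion <- membranes[[config$calibration$ism]]$target_ion
    sub <- sim$cal_chip
    cal_m <- run_panel(sub, solution_spec(setNames(p$c_ref, ion)),
                       c_ref = p$c_ref, v_gs = v_gs, v_ds = p$v_ds,
                       noise_rel = p$noise_rel, membranes = membranes,
                       seed = child_seed(seed, 5))
    test_m <- run_panel(sub,
                        solution_spec(setNames(config$calibration$true_conc,
                                               ion)),
                        c_ref = p$c_ref, v_gs = v_gs, v_ds = p$v_ds,
                        noise_rel = p$noise_rel, membranes = membranes,
                        seed = child_seed(seed, 6))
    test_sl <- dplyr::filter(test_m, .data$v_gs_V ==
                               closest(attr(test_m, "v_gs"),
                                       config$calibration$test_v_gs))
    popn <- ecdf_synthesize(dplyr::bind_rows(cal_m, test_sl),
                            config$redundancy$n_synthetic,
                            seed = child_seed(seed, 7))
    red <- redundancy_ci(
      popn, sample_sizes = config$redundancy$sample_sizes,
      n_repeats = config$redundancy$n_repeats,
      true_conc = config$calibration$true_conc, c_ref = p$c_ref,
      slope_mV_per_decade = calres$slope_mV_per_decade,
      test_v_gs = config$calibration$test_v_gs,
      seed = child_seed(seed, 8))
    readr::write_csv(tibble::as_tibble(red),
                     file.path(out_dir, "redundancy.csv"))
    red
  })
  summary$redundancy <- purrr::map2(redres$n_devices,
                                    redres$half_width_pct,
                                    ~ list(n = .x, half_width_pct = .y))

  revres <- stage_log("reversibility", {
    resp <- conductance_response(sim$meas, v_gs = -0.1,
                                 ref_solution = grep("1mM",
                                   vapply(sim$solutions, `[[`, character(1),
                                          "label"), value = TRUE)[1])
    sols <- solutions_table(sim$solutions)
    per_ism <- lapply(config$layout$isms, function(m) {
      ion <- membranes[[m]]$target_ion
      pure <- sols$solution[sols$species == ion & sols$conc_mol_per_L > 0]
      sub <- resp |>
        dplyr::filter(.data$ism == m, .data$solution %in% pure) |>
        dplyr::left_join(sols[sols$species == ion,
                              c("solution", "conc_mol_per_L")],
                         by = "solution")
      reversibility(sub)$array_pct
    })
    setNames(unlist(per_ism), config$layout$isms)
  })
  summary$reversibility_pct <- as.list(revres)

  mlres <- stage_log("classify", {
    samples <- build_samples(feats, sim$solutions,
                             n_triplets_per_solution = config$ml$n_triplets,
                             noise_frac = config$ml$noise_frac,
                             seed = child_seed(seed, 9))
    cfg <- rf_config(config$ml$trees, config$ml$depth)
    reports <- lapply(config$ml$tasks, function(task)
      train_task(samples, task, n_repeats = config$ml$n_repeats,
                 config = cfg, seed = child_seed(seed, 10)))
    names(reports) <- config$ml$tasks
    acc <- purrr::imap_dfr(reports, ~ tibble::tibble(
      task = .y, accuracy_mean = .x$accuracy_mean,
      accuracy_sd = .x$accuracy_sd, ci_lo = .x$ci[1], ci_hi = .x$ci[2]))
    readr::write_csv(acc, file.path(out_dir, "ml_accuracy.csv"))
    for (task in names(reports))
      readr::write_csv(
        tibble::as_tibble(as.data.frame(reports[[task]]$confusion)),
        file.path(out_dir, paste0("confusion_", task, ".csv")))
    reports
  })
  summary$ml <- lapply(mlres, function(r)
    list(accuracy = r$accuracy_mean, sd = r$accuracy_sd))

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

closest <- function(grid, v) grid[which.min(abs(grid - v))]

#' Packaged example datasets
#'
#' Generates a self-consistent example dataset in memory: chip, solution
#' panel, panel measurement and feature table. `"tiny"` is a 4 x 4
#' single-ISM chip with 2 solutions (sub-second, used by unit tests);
#' `"default"` is a 16 x 16 integrated chip with the 15-solution pure
#' panel.
#'
#' @param scale `"tiny"` or `"default"`.
#' @param seed Integer seed.
#' @return List with `chip`, `solutions`, `measurement`, `features`.
#' @export
make_fixtures <- function(scale = c("tiny", "default"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    layout <- chip_layout(4, 4, "Ca")
    pop <- population_model(yield_p = 1)
    chip <- sample_chip(layout, pop, chip_id = "tiny",
                        seed = child_seed(seed, 1))
    solutions <- list(solution_spec(c(Ca = 1e-3)),
                      solution_spec(c(Ca = 1e-2)))
  } else {
    layout <- chip_layout(16, 16, c("K", "Na", "Ca"))
    pop <- population_model()
    chip <- sample_chip(layout, pop, chip_id = "default",
                        seed = child_seed(seed, 1))
    solutions <- pure_solution_panel()
  }
  meas <- run_panel(chip, solutions, seed = child_seed(seed, 2))
  feats <- extract_features(meas)
  list(chip = chip, solutions = solutions, measurement = meas,
       features = feats)
}
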