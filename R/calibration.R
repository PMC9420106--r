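# Savitzky-Golay style local-polynomial smoothing along the gate axis,
# applied per device (rows) to a devices x gate-voltage current matrix.
# The first/last (pts-1)/2 columns are left untouched.
sg_smooth <- function(M, pts = 9, degree = 2) {
  if (pts <= 1 || ncol(M) < pts) return(M)
  k <- (pts - 1) %/% 2
  X <- outer(-k:k, 0:degree, `^`)
  cf <- (solve(crossprod(X)) %*% t(X))[1, ]
  out <- M
  for (j in (k + 1):(ncol(M) - k))
    out[, j] <- M[, (j - k):(j + k), drop = FALSE] %*% cf
  out
}

# Squared correlation of a test slice against every calibration column.
match_r2 <- function(test, calib) {
  tc <- test - mean(test)
  ss_t <- sum(tc^2)
  mc <- sweep(calib, 2, colMeans(calib))
  ss_c <- colSums(mc^2)
  num <- as.vector(crossprod(mc, tc))
  r2 <- (num * num) / (ss_c * ss_t)
  r2[ss_c == 0] <- NA_real_
  r2
}

# Sub-grid refinement of the R^2 peak: least-squares parabola over the
# points within `window` volts of the discrete maximum. The wide window
# averages the per-slice noise of the R^2 profile (the profile is locally
# flat, so the raw argmax jitters by grid steps under current noise); the
# vertex is clamped to the window.
refine_peak <- function(v, r2, window = 0.02) {
  j <- which.max(r2)
  sel <- which(abs(v - v[j]) <= window + 1e-12 & is.finite(r2))
  if (length(sel) < 3) return(v[j])
  x <- v[sel] - v[j]
  fit <- stats::lm.fit(cbind(1, x, x^2), r2[sel])$coefficients
  if (!is.finite(fit[3]) || fit[3] >= 0) return(v[j])  # not concave
  vertex <- -fit[2] / (2 * fit[3])
  v[j] + max(min(vertex, window), -window)
}

# Core matcher on aligned numeric data; used by match_profile() and the
# redundancy resampler. `calib_mat` is expected pre-smoothed. Two
# objectives are available: plain least-squares distance between the test
# slice and each calibration slice (`"lsq"`, the default -- it keeps the
# current-magnitude information and gives a sharp optimum) and the squared
# correlation profile (`"correlation"`, whose peak is invariant to affine
# rescaling of either slice). The R^2 profile is computed and reported in
# both cases.
match_core <- function(test_vec, calib_mat, v_grid, test_v_gs,
                       refine = TRUE, min_devices = 10,
                       objective = c("lsq", "correlation")) {
  objective <- match.arg(objective)
  n <- length(test_vec)
  if (n < min_devices)
    abort(sprintf("only %d common devices; need >= %d.", n, min_devices))
  if (objective == "correlation" && sd(test_vec) == 0)
    abort("test current slice has zero variance across devices.")
  r2 <- match_r2(test_vec, calib_mat)
  sse <- colMeans((calib_mat - test_vec)^2)
  if (objective == "correlation" && all(!is.finite(r2)))
    abort("calibration slices have zero variance across devices.")
  score <- if (objective == "lsq") -sse else r2
  jbest <- which.max(score)
  exact <- (objective == "lsq" && sse[jbest] == 0) ||
    (objective == "correlation" && r2[jbest] >= 1 - 1e-12)
  v_star <- if (refine && !exact) refine_peak(v_grid, score)
            else v_grid[jbest]
  list(profile = tibble::tibble(v_gs_V = v_grid, r2 = r2, sse = sse),
       v_star = v_star, delta_v = v_star - test_v_gs,
       r2_max = if (all(!is.finite(r2))) NA_real_ else max(r2, na.rm = TRUE),
       n_devices = n, objective = objective)
}

#' Profile-matching of a test current slice against a calibration I-V set
#'
#' The heart of the single-solution calibration: the per-device current
#' slice measured in the unknown solution at one gate voltage is regressed,
#' device-by-device, against the calibration current slice at every gate
#' voltage of the reference-solution I-V set. Because the transfer curves
#' translate along the gate axis with concentration while the
#' device-to-device current pattern is preserved, the squared correlation
#' R^2 peaks at the calibration gate voltage displaced from the test gate
#' voltage by the Nernstian shift, and the least-squares distance dips
#' there. The calibration curves are denoised
#' along the gate axis by a local-polynomial (Savitzky-Golay) filter
#' before slicing, and the R^2 peak is refined below the 10 mV grid by a
#' least-squares parabola over the points within 20 mV of the discrete
#' maximum.
#'
#' @param test A [current_slice()] from the unknown solution (or a plain
#'   numeric vector in calibration device order, in which case
#'   `test_v_gs` must be given).
#' @param calibration Long measurement tibble of the reference-solution
#'   sweep (a single solution), or an `ion_population` with a single
#'   full-sweep solution.
#' @param test_v_gs Gate voltage of the test slice (V); defaults to the
#'   slice attribute.
#' @param direction Sweep direction used from `calibration`.
#' @param refine Apply sub-grid peak refinement.
#' @param min_devices Minimum number of common devices.
#' @param smooth_pts,smooth_degree Window (grid points, odd) and degree of
#'   the local-polynomial denoising of the calibration curves;
#'   `smooth_pts = 1` disables it.
#' @param objective `"lsq"` (default) locates the optimum slice by plain
#'   least-squares distance, which exploits the current-magnitude
#'   information shared by test and calibration measurements of the same
#'   devices; `"correlation"` locates the R^2 peak, which is invariant to
#'   affine rescaling of either slice. The R^2 profile is reported either
#'   way.
#' @return An `ion_match` object: `profile` (tibble of `v_gs_V`, `r2`),
#'   `v_star`, `delta_v`, `r2_max`, `n_devices`.
#' @export
match_profile <- function(test, calibration, test_v_gs = NULL,
                          direction = "forward", refine = TRUE,
                          min_devices = 10, smooth_pts = 9,
                          smooth_degree = 2,
                          objective = c("lsq", "correlation")) {
  if (inherits(calibration, "ion_population")) {
    sols <- unique(calibration$columns$solution)
    if (length(sols) > 1) {
      full <- names(which.max(table(calibration$columns$solution)))
      keep <- calibration$columns$solution == full
    } else keep <- rep(TRUE, ncol(calibration$values))
    calib_mat <- calibration$values[, keep, drop = FALSE]
    v_grid <- calibration$columns$v_gs_V[keep]
    devices <- tibble::tibble(row = seq_len(nrow(calib_mat)), col = 0L)
  } else {
    sols <- unique(calibration$solution)
    if (length(sols) != 1)
      abort("`calibration` must contain a single reference solution.")
    wide <- measurement_matrix(calibration, direction)
    calib_mat <- wide$values
    v_grid <- wide$columns$v_gs_V
    devices <- wide$devices
  }
  ord <- order(v_grid)
  v_grid <- v_grid[ord]; calib_mat <- calib_mat[, ord, drop = FALSE]
  calib_mat <- sg_smooth(calib_mat, smooth_pts, smooth_degree)
  if (inherits(test, "current_slice") || is.data.frame(test)) {
    test_v_gs <- test_v_gs %||% attr(test, "v_gs_V")
    key_t <- paste(test$row, test$col)
    key_c <- paste(devices$row, devices$col)
    common <- intersect(key_c, key_t)
    calib_mat <- calib_mat[match(common, key_c), , drop = FALSE]
    test_vec <- test$i_ds_A[match(common, key_t)]
  } else {
    test_vec <- as.numeric(test)
    if (length(test_vec) != nrow(calib_mat))
      abort("numeric `test` must match the calibration device count.")
  }
  if (is.null(test_v_gs)) abort("`test_v_gs` is required.")
  out <- match_core(test_vec, calib_mat, v_grid, test_v_gs,
                    refine, min_devices, objective)
  structure(c(out, list(test_v_gs = test_v_gs)), class = "ion_match")
}

#' @export
print.ion_match <- function(x, ...) {
  cat(sprintf("<ion_match> v* = %+.4f V, delta_v = %+.4f V, max R^2 = %.4f (%d devices)\n",
              x$v_star, x$delta_v, x$r2_max, x$n_devices))
  invisible(x)
}

#' Concentration from a profile match
#'
#' Converts the matched voltage shift to a concentration through the
#' sensitivity slope: \eqn{\log_{10} c = \log_{10} c_{ref} - \Delta V / s}
#' with \eqn{\Delta V} in mV and the slope \eqn{s} in mV per decade, signed
#' as measured (negative for cations).
#'
#' @param profile An `ion_match` from [match_profile()], or a numeric
#'   voltage shift in volts.
#' @param c_ref Reference molar concentration.
#' @param slope_mV_per_decade Sensitivity slope (mV/decade, non-zero).
#' @return Estimated concentration (mol/L).
#' @export
estimate_concentration <- function(profile, c_ref, slope_mV_per_decade) {
  if (slope_mV_per_decade == 0) abort("`slope_mV_per_decade` must be non-zero.")
  delta_v <- if (inherits(profile, "ion_match")) profile$delta_v
             else as.numeric(profile)
  10^(log10(c_ref) - delta_v * 1000 / slope_mV_per_decade)
}

#' Profile-matching calibration accuracy over a concentration range
#'
#' Simulates the full calibration experiment on one chip: a single
#' reference-solution I-V calibration set, then, for each true
#' concentration, a test measurement sliced at `test_v_gs`, profile-matched
#' and converted to an estimated concentration. Accuracy is summarized by
#' the ordinary least-squares fit of log10(true) on log10(estimated)
#' concentration (estimates on x as in the standard accuracy plot).
#'
#' @param chip Chip tibble from [sample_chip()]; only the `ism` region is
#'   used.
#' @param concentrations True molar concentrations to test (within the
#'   quasi-linear range, 10 uM to 100 mM).
#' @param c_ref Reference (calibration) molar concentration.
#' @param ism ISM region to use (its target ion is the analyte).
#' @param test_v_gs Gate voltage of the test slices (V).
#' @param slope_mV_per_decade Sensitivity slope used in the conversion;
#'   default is the chip's generative mean slope for the region,
#'   `-mean(sens_scale) * nernst_slope(z) * 1000`, standing in for a
#'   previously characterized sensitivity.
#' @param v_gs,v_ds,noise_rel Sweep settings, as in [run_panel()].
#' @param test_n_avg Number of transient samples averaged into each test
#'   current slice. Test slices come from the steady part of a 20-30 s
#'   dwell, so their per-device noise is `noise_rel / sqrt(test_n_avg)`.
#' @param objective Matching objective, as in [match_profile()].
#' @param membranes Membrane list; defaults to the chip attribute.
#' @param seed Optional integer seed.
#' @return An `ion_calibration` object: per-concentration estimates and the
#'   log-log fit (`slope`, `r_squared`).
#' @export
calibration_accuracy <- function(chip, concentrations = 10^(-5:-1),
                                 c_ref = 1e-3, ism = "Ca", test_v_gs = 0,
                                 slope_mV_per_decade = NULL,
                                 v_gs = seq(-0.6, 0.9, by = 0.01),
                                 v_ds = 0.3, noise_rel = 0.01,
                                 test_n_avg = 25, membranes = NULL,
                                 objective = c("lsq", "correlation"),
                                 seed = NULL) {
  membranes <- membranes %||% attr(chip, "membranes") %||% ism_library()
  sub <- chip[chip$ism == ism, ]
  if (!nrow(sub)) abort(paste0("chip has no '", ism, "' region."))
  mem <- membranes[[ism]]
  ion <- mem$target_ion
  slope_mV_per_decade <- slope_mV_per_decade %||%
    (-1000 * mean(sub$sens_scale[sub$functional]) * nernst_slope(mem$z))
  sol_ref <- solution_spec(setNames(c_ref, ion))
  cal <- run_panel(sub, sol_ref, c_ref = c_ref, v_gs = v_gs, v_ds = v_ds,
                   noise_rel = noise_rel, membranes = membranes,
                   seed = child_seed(seed, 1))
  rows <- purrr::imap(concentrations, function(conc, k) {
    sol <- solution_spec(setNames(conc, ion))
    test_meas <- run_panel(sub, sol, c_ref = c_ref, v_gs = v_gs,
                           v_ds = v_ds,
                           noise_rel = noise_rel / sqrt(test_n_avg),
                           membranes = membranes,
                           seed = child_seed(seed, 1 + k))
    sl <- current_slice(test_meas, sol$label, v_gs = test_v_gs)
    m <- match_profile(sl, cal, objective = objective)
    tibble::tibble(conc_mol_per_L = conc, v_star_V = m$v_star,
                   delta_v_V = m$delta_v, r2_max = m$r2_max,
                   c_est_mol_per_L =
                     estimate_concentration(m, c_ref, slope_mV_per_decade))
  })
  est <- dplyr::bind_rows(rows)
  fit <- lm(log10(conc_mol_per_L) ~ log10(c_est_mol_per_L), data = est)
  structure(
    list(estimates = est, slope = unname(coef(fit)[2]),
         r_squared = summary(fit)$r.squared, fit = fit,
         slope_mV_per_decade = slope_mV_per_decade, c_ref = c_ref,
         ism = ism),
    class = "ion_calibration"
  )
}

#' @export
print.ion_calibration <- function(x, ...) {
  cat(sprintf("<ion_calibration> %s ISM, %d concentrations vs %s reference\n",
              x$ism, nrow(x$estimates), format(x$c_ref)))
  cat(sprintf("  log-log fit of true on estimated: slope = %.3f, R^2 = %.4f\n",
              x$slope, x$r_squared))
  invisible(x)
}

#' Redundancy study: estimate confidence versus array size
#'
#' Quantifies how sensor redundancy tightens the profile-matching estimate.
#' From a large (typically ECDF-synthesized) device population holding a
#' calibration I-V set at `c_ref` and a test slice at a known true
#' concentration, arrays of `sample_sizes` devices are drawn without
#' replacement `n_repeats` times; each draw is profile-matched and
#' converted to a concentration estimate. The 95% (by default) confidence
#' interval of the estimates is reported per array size, with its
#' half-width expressed as a percentage of the true concentration.
#'
#' @param population An `ion_population` from [ecdf_synthesize()] (or a
#'   long measurement tibble) containing the calibration sweep and the
#'   test measurement.
#' @param sample_sizes Array sizes to evaluate (each <= population size).
#' @param n_repeats Draws per size (>= 100 recommended).
#' @param true_conc True molar concentration of the test solution.
#' @param c_ref Reference molar concentration of the calibration sweep.
#' @param slope_mV_per_decade Sensitivity slope for the conversion.
#' @param cal_solution,test_solution Solution labels; by default the label
#'   with the most gate-voltage columns is the calibration sweep and the
#'   other one the test solution.
#' @param test_v_gs Gate voltage of the test slice (V).
#' @param ci_level Confidence level for the percentile interval.
#' @param min_devices Minimum devices for a match (lowered to 2 here so
#'   that very small arrays can be scored).
#' @param smooth_pts,smooth_degree Local-polynomial denoising of the
#'   calibration curves, as in [match_profile()].
#' @param objective Matching objective, as in [match_profile()].
#' @param seed Optional integer seed.
#' @return An `ion_redundancy` tibble: `n_devices`, `mean_est`, `ci_lo`,
#'   `ci_hi`, `half_width_pct`.
#' @export
redundancy_ci <- function(population, sample_sizes = c(5, 25, 100, 215),
                          n_repeats = 1000, true_conc = 1e-2, c_ref = 1e-3,
                          slope_mV_per_decade = -30.1,
                          cal_solution = NULL, test_solution = NULL,
                          test_v_gs = 0, ci_level = 0.95, min_devices = 2,
                          smooth_pts = 9, smooth_degree = 2,
                          objective = c("lsq", "correlation"),
                          seed = NULL) {
  if (is.data.frame(population)) {
    wide <- measurement_matrix(population)
    values <- wide$values; columns <- wide$columns
  } else {
    values <- population$values; columns <- population$columns
  }
  counts <- table(columns$solution)
  cal_solution <- cal_solution %||% names(which.max(counts))
  test_solution <- test_solution %||%
    setdiff(names(counts), cal_solution)[1]
  if (is.na(test_solution)) abort("population lacks a test solution.")
  cal_cols <- which(columns$solution == cal_solution)
  v_grid <- columns$v_gs_V[cal_cols]
  ord <- order(v_grid)
  cal_cols <- cal_cols[ord]; v_grid <- v_grid[ord]
  values[, cal_cols] <- sg_smooth(values[, cal_cols, drop = FALSE],
                                  smooth_pts, smooth_degree)
  tcols <- which(columns$solution == test_solution)
  test_col <- tcols[which.min(abs(columns$v_gs_V[tcols] - test_v_gs))]
  tv <- columns$v_gs_V[test_col]
  n_pop <- nrow(values)
  if (any(sample_sizes > n_pop)) abort("sample size exceeds population size.")
  if (n_repeats < 1) abort("`n_repeats` must be >= 1.")
  objective <- match.arg(objective)
  alpha <- (1 - ci_level) / 2
  with_seed_or_not(seed, {
    rows <- lapply(sample_sizes, function(nn) {
      est <- vapply(seq_len(n_repeats), function(r) {
        for (try in seq_len(100L)) {
          idx <- sample.int(n_pop, nn)
          # tiny draws can hit synthetic devices sharing one source rank
          # (zero spread); redraw those degenerate arrays
          if (sd(values[idx, test_col]) > 0) break
        }
        m <- match_core(values[idx, test_col], values[idx, cal_cols, drop = FALSE],
                        v_grid, tv, refine = TRUE,
                        min_devices = min_devices, objective = objective)
        estimate_concentration(m$delta_v, c_ref, slope_mV_per_decade)
      }, numeric(1))
      qs <- quantile(est, c(alpha, 1 - alpha), names = FALSE)
      tibble::tibble(n_devices = nn, mean_est = mean(est),
                     ci_lo = qs[1], ci_hi = qs[2],
                     half_width_pct = 100 * (qs[2] - qs[1]) / 2 / true_conc)
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "true_conc") <- true_conc
    attr(out, "ci_level") <- ci_level
    class(out) <- c("ion_redundancy", class(out))
    out
  })
}
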