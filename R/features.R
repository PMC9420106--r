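# Per-curve quality criteria; a device must pass on every curve to count
# as working.
curve_ok <- function(v_gs, i_ds, min_current = 1e-6, min_ratio = 1.05) {
  if (any(!is.finite(i_ds))) return(FALSE)
  imax <- max(abs(i_ds))
  if (imax < min_current) return(FALSE)
  imin <- min(abs(i_ds))
  if (imin <= 0 || imax / imin < min_ratio) return(FALSE)  # no modulation
  k <- which.min(i_ds)
  if (k == 1L || k == length(i_ds)) return(FALSE)          # edge minimum
  TRUE
}

#' Flag working devices
#'
#' A device is working when every one of its transfer curves has finite
#' samples, a peak current of at least `min_current`, visible gate
#' modulation (max/min current ratio at least `min_ratio`) and an interior
#' conduction minimum. These reproduce the usual array yield screen; at the
#' default population the post-filter yield exceeds 80%.
#'
#' @param measurement Long measurement tibble from [run_panel()].
#' @param min_current Minimum peak |I_DS| (A).
#' @param min_ratio Minimum max/min current ratio.
#' @return Tibble with columns `chip_id`, `row`, `col`, `ism`, `working`.
#' @export
filter_working <- function(measurement, min_current = 1e-6,
                           min_ratio = 1.05) {
  measurement |>
    dplyr::group_by(.data$chip_id, .data$row, .data$col, .data$ism,
                    .data$solution,
                    dplyr::across(dplyr::any_of("direction"))) |>
    dplyr::summarise(
      ok = curve_ok(.data$v_gs_V, .data$i_ds_A, min_current, min_ratio),
      .groups = "drop") |>
    dplyr::group_by(.data$chip_id, .data$row, .data$col, .data$ism) |>
    dplyr::summarise(working = all(.data$ok), .groups = "drop")
}

#' Chip yield after device filtering
#'
#' @param working Output of [filter_working()] (or a feature table with a
#'   `working` column).
#' @param n_pixels Total pixel count of the chip (e.g. 256 for 16 x 16).
#' @return Fraction of pixels that are working.
#' @export
chip_yield <- function(working, n_pixels) {
  dev <- dplyr::distinct(working, .data$row, .data$col, .data$working)
  sum(dev$working) / n_pixels
}

#' Dirac-point extraction from one transfer curve
#'
#' Estimates the gate voltage of minimum conduction by fitting a polynomial
#' (default degree 4) to the samples within `window` volts of the discrete
#' current minimum and locating the analytic minimum of the fit. Degree 4
#' accommodates the hole/electron branch asymmetry that a parabola cannot;
#' the window keeps the fit local. If the polynomial minimum escapes the
#' window the discrete grid minimum is returned instead.
#'
#' @param v_gs,i_ds Gate-voltage grid (strictly increasing) and currents.
#' @param degree Polynomial degree (reduced automatically if the window
#'   holds too few points).
#' @param window Half-width (V) of the fit window around the grid minimum.
#' @return Dirac voltage (V).
#' @export
dirac_point <- function(v_gs, i_ds, degree = 4, window = 0.25) {
  n <- length(v_gs)
  stopifnot(n >= 3, length(i_ds) == n)
  k0 <- which.min(i_ds)
  if (k0 == 1L || k0 == n)
    abort("conduction minimum at sweep edge; device should be filtered out.",
          class = "ionarray_edge_minimum")
  v0 <- v_gs[k0]
  sel <- abs(v_gs - v0) <= window + 1e-12
  deg <- min(degree, sum(sel) - 1L)
  if (deg < 2) return(v0)
  x <- v_gs[sel] - v0
  X <- outer(x, 0:deg, `^`)
  beta <- stats::lm.fit(X, i_ds[sel])$coefficients
  dcoef <- beta[-1] * seq_len(deg)            # derivative coefficients
  roots <- polyroot(dcoef)
  re <- Re(roots)[abs(Im(roots)) < 1e-8 * pmax(1, abs(Re(roots)))]
  re <- re[abs(re) <= window & re >= min(x) & re <= max(x)]
  if (!length(re)) return(v0)
  vals <- vapply(re, function(r) sum(beta * r^(0:deg)), numeric(1))
  cand <- re[which.min(vals)]
  if (min(vals) > i_ds[k0]) return(v0)        # fit minimum worse than grid
  v0 + cand
}

probe_name <- function(v) {
  sprintf("i_at_%sV_A",
          gsub("\\.", "p", gsub("-", "m",
               format(v, trim = TRUE, drop0trailing = TRUE))))
}

# Central-difference transconductance on the raw grid (one-sided at ends).
transconductance <- function(v, i) {
  n <- length(v)
  gm <- numeric(n)
  gm[1] <- (i[2] - i[1]) / (v[2] - v[1])
  gm[n] <- (i[n] - i[n - 1]) / (v[n] - v[n - 1])
  if (n > 2)
    gm[2:(n - 1)] <- (i[3:n] - i[1:(n - 2)]) / (v[3:n] - v[1:(n - 2)])
  gm
}

#' Extract per-device transfer-curve features
#'
#' For every (device, solution, direction) curve: Dirac voltage (polynomial
#' fit, see [dirac_point()]), minimum current, maximum (electron-branch) and
#' minimum (hole-branch) transconductance by central differences on the raw
#' grid, currents at fixed probe gate voltages, and the branch asymmetry
#' |gm_max / gm_min|. Devices failing the working-device screen are dropped
#' unless `keep_nonworking = TRUE`.
#'
#' @param measurement Long measurement tibble from [run_panel()].
#' @param probe_v Gate voltages (V) at which to record currents.
#' @param degree,window Passed to [dirac_point()].
#' @param min_current,min_ratio Passed to [filter_working()].
#' @param keep_nonworking Keep non-working devices (feature columns `NA`).
#' @return Feature tibble keyed by `chip_id`, `row`, `col`, `ism`,
#'   `solution` (and `direction`), with a logical `working` column.
#' @export
extract_features <- function(measurement, probe_v = c(-0.1, 0.6),
                             degree = 4, window = 0.25,
                             min_current = 1e-6, min_ratio = 1.05,
                             keep_nonworking = FALSE) {
  wk <- filter_working(measurement, min_current, min_ratio)
  meas <- dplyr::left_join(measurement, wk,
                           by = c("chip_id", "row", "col", "ism"))
  if (!keep_nonworking) meas <- dplyr::filter(meas, .data$working)
  if (!nrow(meas)) abort("no working devices to extract features from.")
  pnames <- probe_name(probe_v)
  feat_one <- function(v, i, working) {
    if (!working[1] || !curve_ok(v, i, min_current, min_ratio)) {
      out <- tibble::tibble(v_dirac_V = NA_real_, i_min_A = NA_real_,
                            gm_max_A_per_V = NA_real_,
                            gm_min_A_per_V = NA_real_)
      for (p in pnames) out[[p]] <- NA_real_
      out$asymmetry <- NA_real_
      return(out)
    }
    gm <- transconductance(v, i)
    out <- tibble::tibble(
      v_dirac_V = dirac_point(v, i, degree, window),
      i_min_A = min(i),
      gm_max_A_per_V = max(gm),
      gm_min_A_per_V = min(gm))
    iat <- approx(v, i, xout = probe_v, rule = 2)$y
    for (k in seq_along(pnames)) out[[pnames[k]]] <- iat[k]
    out$asymmetry <- abs(out$gm_max_A_per_V / out$gm_min_A_per_V)
    out
  }
  meas |>
    dplyr::group_by(.data$chip_id, .data$row, .data$col, .data$ism,
                    .data$solution,
                    dplyr::across(dplyr::any_of("direction")),
                    .data$working) |>
    dplyr::reframe(feat_one(.data$v_gs_V, .data$i_ds_A, .data$working)) |>
    dplyr::relocate("working", .after = dplyr::last_col())
}

#' Normalized conductance response at a fixed gate voltage
#'
#' Per-device percentage change of the operating current at a fixed gate
#' bias relative to the same device's current in a reference solution
#' (within the same sweep direction) -- the transient-style response used
#' for reversibility analysis. With the gate on the hole branch the
#' response decreases with increasing cation concentration.
#'
#' @param measurement Long measurement tibble.
#' @param v_gs Probe gate voltage (V), snapped to the grid.
#' @param ref_solution Label of the normalizing solution (e.g. the 1 mM
#'   dilution).
#' @return Tibble with `chip_id`, `row`, `col`, `ism`, `solution`
#'   (`direction` if present), `i_ds_A` and `response_pct`.
#' @export
conductance_response <- function(measurement, v_gs = -0.1, ref_solution) {
  grid <- sort(unique(measurement$v_gs_V))
  v0 <- grid[which.min(abs(grid - v_gs))]
  sl <- dplyr::filter(measurement, .data$v_gs_V == v0)
  keys <- intersect(c("chip_id", "row", "col", "ism", "direction"),
                    names(sl))
  ref <- sl |>
    dplyr::filter(.data$solution == ref_solution) |>
    dplyr::select(dplyr::all_of(keys), i_ref = "i_ds_A")
  if (!nrow(ref))
    abort(paste0("reference solution '", ref_solution, "' not in measurement."))
  sl |>
    dplyr::inner_join(ref, by = keys) |>
    dplyr::mutate(response_pct =
                    100 * (.data$i_ds_A - .data$i_ref) / .data$i_ref) |>
    dplyr::select(dplyr::all_of(keys), "solution", "i_ds_A", "response_pct")
}

# Per-group OLS slope of value against log10(conc), vectorized by device.
device_slopes <- function(df) {
  df |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(
      slope = {
        lg <- log10(.data$conc)
        sum((lg - mean(lg)) * (.data$value - mean(.data$value))) /
          sum((lg - mean(lg))^2)
      },
      .groups = "drop")
}

#' Array sensitivity from Dirac points (or any response) vs concentration
#'
#' Ordinary least squares of the array-mean response against
#' log10(concentration). With Dirac voltages as the response the slope (in
#' mV per decade) is the potentiometric sensitivity; an ideal monovalent
#' Nernstian array gives -59.16 mV/decade at 298.15 K. Per-device slopes
#' are returned for the device-spread histogram.
#'
#' @param data Tibble with device keys `row`, `col`, a concentration column
#'   and a response column.
#' @param conc,value Unquoted column names of the concentration (mol/L,
#'   > 0) and the response (V unless `value_unit` says otherwise).
#' @param value_unit `"V"` (slopes reported in mV/decade) or `"raw"`
#'   (slopes in response units per decade).
#' @return An `ion_sensitivity` object; see [tidy()][generics::tidy] and
#'   [glance()][generics::glance].
#' @export
sensitivity <- function(data, conc = conc_mol_per_L, value = v_dirac_V,
                        value_unit = c("V", "raw")) {
  value_unit <- match.arg(value_unit)
  df <- tibble::tibble(
    row = data$row, col = data$col,
    conc = dplyr::pull(data, {{ conc }}),
    value = dplyr::pull(data, {{ value }}))
  df <- df[complete.cases(df), ]
  if (any(df$conc <= 0)) abort("concentrations must be > 0 for a log fit.")
  if (length(unique(df$conc)) < 2)
    abort("need at least 2 distinct concentrations.")
  scale <- if (value_unit == "V") 1000 else 1
  means <- df |>
    dplyr::group_by(.data$conc) |>
    dplyr::summarise(mean_value = mean(.data$value),
                     sd_value = sd(.data$value), .groups = "drop")
  fit <- lm(mean_value ~ log10(conc), data = means)
  # exact-line inputs give a zero-residual fit; the s.e. of 0 is valid
  sm <- suppressWarnings(summary(fit)$coefficients)
  per_dev <- device_slopes(df)
  structure(
    list(slope = unname(coef(fit)[2]) * scale,
         intercept = unname(coef(fit)[1]),
         stderr = unname(sm[2, 2]) * scale,
         unit = if (value_unit == "V") "mV/decade" else "per decade",
         per_device = tibble::tibble(row = per_dev$row, col = per_dev$col,
                                     slope = per_dev$slope * scale),
         means = means, fit = fit,
         n_devices = nrow(per_dev)),
    class = "ion_sensitivity"
  )
}

#' @export
print.ion_sensitivity <- function(x, ...) {
  cat(sprintf("<ion_sensitivity> slope = %.2f +/- %.2f %s (array mean of %d devices, %d concentrations)\n",
              x$slope, x$stderr, x$unit, x$n_devices, nrow(x$means)))
  cat(sprintf("  device spread: %.2f +/- %.2f %s\n",
              mean(x$per_device$slope), sd(x$per_device$slope), x$unit))
  invisible(x)
}

#' Forward/backward reversibility
#'
#' Quantifies reversibility as the symmetric percentage difference between
#' the response-vs-log10(concentration) slopes fitted separately to the
#' forward (low-to-high) and backward (high-to-low) series:
#' \eqn{100 |s_f - s_b| / ((|s_f| + |s_b|)/2)}. The array-level value uses
#' the array-mean response at each concentration; per-device values feed
#' the reversibility histogram.
#'
#' @param data Tibble with `row`, `col`, a `direction` column
#'   (forward/backward), a concentration column and a response column.
#' @param conc,value Unquoted concentration and response columns.
#' @return An `ion_reversibility` object with `array_pct`,
#'   `slope_forward`, `slope_backward` and a `per_device` tibble.
#' @export
reversibility <- function(data, conc = conc_mol_per_L,
                          value = response_pct) {
  if (!"direction" %in% names(data)) abort("`data` needs a `direction` column.")
  df <- tibble::tibble(
    row = data$row, col = data$col, direction = data$direction,
    conc = dplyr::pull(data, {{ conc }}),
    value = dplyr::pull(data, {{ value }}))
  dirs <- c("forward", "backward")
  if (!all(dirs %in% df$direction))
    abort("both forward and backward series are required.")
  common <- df |>
    dplyr::distinct(.data$direction, .data$conc) |>
    dplyr::count(.data$conc) |>
    dplyr::filter(.data$n == 2)
  if (nrow(common) < 2)
    abort("forward and backward series must share >= 2 concentrations.")
  df <- dplyr::filter(df, .data$conc %in% common$conc)
  sym_pct <- function(sf, sb) {
    denom <- (abs(sf) + abs(sb)) / 2
    if (denom == 0) abort("zero mean slope; reversibility undefined.")
    100 * abs(sf - sb) / denom
  }
  array_slope <- function(dir) {
    m <- df |>
      dplyr::filter(.data$direction == dir) |>
      dplyr::group_by(.data$conc) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
    unname(coef(lm(value ~ log10(conc), data = m))[2])
  }
  sf <- array_slope("forward"); sb <- array_slope("backward")
  per_dev <- df |>
    dplyr::group_by(.data$direction) |>
    dplyr::group_modify(~ device_slopes(.x)) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(names_from = "direction", values_from = "slope") |>
    dplyr::filter(is.finite(.data$forward), is.finite(.data$backward)) |>
    dplyr::mutate(pct = 100 * abs(.data$forward - .data$backward) /
                    pmax((abs(.data$forward) + abs(.data$backward)) / 2,
                         .Machine$double.eps))
  structure(
    list(array_pct = sym_pct(sf, sb), slope_forward = sf,
         slope_backward = sb, per_device = per_dev),
    class = "ion_reversibility"
  )
}

#' @export
print.ion_reversibility <- function(x, ...) {
  cat(sprintf("<ion_reversibility> array-level slope difference = %.2f%% (forward %.3g, backward %.3g)\n",
              x$array_pct, x$slope_forward, x$slope_backward))
  cat(sprintf("  per-device median %.1f%%, worst %.1f%% (%d devices)\n",
              median(x$per_device$pct), max(x$per_device$pct),
              nrow(x$per_device)))
  invisible(x)
}

#' 90% response time of a transient step
#'
#' Time after `step_time` at which the current first crosses 90% (by
#' default) of the asymptotic amplitude change, with linear interpolation
#' between samples. For an ideal exponential of time constant `tau` the
#' result is `tau * log(10)`.
#'
#' @param time_s,i_ds Transient trace (monotone time, seconds).
#' @param step_time Time of the solution change (s).
#' @param threshold Crossing fraction of the step amplitude.
#' @param i_final Asymptotic post-step current (A); defaults to the last
#'   sample, which presumes the trace has reached steady state. Supply it
#'   explicitly for truncated traces.
#' @return Response time in seconds.
#' @export
response_time <- function(time_s, i_ds, step_time = 0, threshold = 0.9,
                          i_final = NULL) {
  stopifnot(length(time_s) == length(i_ds), !is.unsorted(time_s))
  post <- which(time_s >= step_time)
  if (!length(post)) abort("trace does not span the step.")
  pre <- which(time_s < step_time)
  i0 <- if (length(pre)) i_ds[max(pre)] else i_ds[post[1]]
  i_inf <- i_final %||% i_ds[length(i_ds)]
  amp <- i_inf - i0
  if (amp == 0) abort("no step amplitude; response time undefined.")
  thr <- i0 + threshold * amp
  crossed <- (i_ds[post] - thr) * sign(amp) >= 0
  if (!any(crossed)) abort("trace never reaches the response threshold.")
  k <- post[which(crossed)[1]]
  if (k == post[1]) return(time_s[k] - step_time)
  t_cross <- time_s[k - 1] +
    (thr - i_ds[k - 1]) / (i_ds[k] - i_ds[k - 1]) *
    (time_s[k] - time_s[k - 1])
  t_cross - step_time
}
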