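#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for ionarray result objects
#'
#' `tidy()` returns the per-unit detail of a result (per-device slopes,
#' the R^2 profile, per-concentration estimates, the long confusion
#' matrix, the attribution ranking); `glance()` returns a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name ionarray-tidiers
NULL

#' @rdname ionarray-tidiers
#' @export
tidy.ion_sensitivity <- function(x, ...) x$per_device

#' @rdname ionarray-tidiers
#' @export
glance.ion_sensitivity <- function(x, ...) {
  tibble::tibble(slope = x$slope, stderr = x$stderr,
                 intercept_V = x$intercept, unit = x$unit,
                 n_devices = x$n_devices,
                 r_squared = summary(x$fit)$r.squared)
}

#' @rdname ionarray-tidiers
#' @export
tidy.ion_match <- function(x, ...) x$profile

#' @rdname ionarray-tidiers
#' @export
glance.ion_match <- function(x, ...) {
  tibble::tibble(v_star_V = x$v_star, delta_v_V = x$delta_v,
                 r2_max = x$r2_max, n_devices = x$n_devices)
}

#' @rdname ionarray-tidiers
#' @export
tidy.ion_calibration <- function(x, ...) x$estimates

#' @rdname ionarray-tidiers
#' @export
glance.ion_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, r_squared = x$r_squared,
                 slope_mV_per_decade = x$slope_mV_per_decade,
                 c_ref = x$c_ref, n_concentrations = nrow(x$estimates))
}

#' @rdname ionarray-tidiers
#' @export
tidy.ion_task <- function(x, ...) {
  conf <- as.data.frame(x$confusion)
  names(conf) <- c("truth", "prediction", "n")
  tibble::as_tibble(conf)
}

#' @rdname ionarray-tidiers
#' @export
glance.ion_task <- function(x, ...) {
  tibble::tibble(task = x$task, method = x$method,
                 accuracy_mean = x$accuracy_mean,
                 accuracy_sd = x$accuracy_sd,
                 ci_lo = x$ci[1], ci_hi = x$ci[2],
                 n_repeats = x$n_repeats, n_samples = x$n_samples)
}

#' @rdname ionarray-tidiers
#' @export
tidy.ion_reversibility <- function(x, ...) x$per_device

#' @rdname ionarray-tidiers
#' @export
glance.ion_reversibility <- function(x, ...) {
  tibble::tibble(array_pct = x$array_pct,
                 slope_forward = x$slope_forward,
                 slope_backward = x$slope_backward,
                 n_devices = nrow(x$per_device))
}

#' @rdname ionarray-tidiers
#' @export
tidy.ion_importance <- function(x, ...) x$importance

#' @rdname ionarray-tidiers
#' @export
tidy.ion_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$variance_fraction),
                 variance_fraction = x$variance_fraction)
}
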