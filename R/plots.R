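#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot transfer curves of a measurement
#'
#' Overlays the V-shaped I-V characteristics of (a sample of) devices,
#' optionally colored by solution to show the Nernstian leftward shift
#' with increasing cation concentration.
#'
#' @param measurement Long measurement tibble.
#' @param max_devices Sample at most this many devices.
#' @param seed Seed for the device sample.
#' @return A ggplot object.
#' @export
plot_iv <- function(measurement, max_devices = 16, seed = 1L) {
  dev <- dplyr::distinct(measurement, .data$row, .data$col)
  if (nrow(dev) > max_devices)
    dev <- with_seed_or_not(seed,
      dev[sample.int(nrow(dev), max_devices), ])
  sub <- dplyr::semi_join(measurement, dev, by = c("row", "col"))
  if ("direction" %in% names(sub))
    sub <- dplyr::filter(sub, .data$direction == .data$direction[1])
  ggplot2::ggplot(sub,
    ggplot2::aes(.data$v_gs_V, .data$i_ds_A * 1e6,
                 group = interaction(.data$row, .data$col, .data$solution),
                 colour = .data$solution)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "V_GS (V)", y = "I_DS (uA)", colour = "solution") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-ionarray
#' @export
autoplot.ion_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object$means,
    ggplot2::aes(log10(.data$conc), .data$mean_value)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_value - .data$sd_value,
      ymax = .data$mean_value + .data$sd_value), width = 0.1) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "log10(concentration, mol/L)",
                  y = "array-mean response",
                  title = sprintf("sensitivity %.1f %s", object$slope,
                                  object$unit)) +
    ggplot2::theme_minimal()
}

#' Autoplot methods for ionarray results
#'
#' Quick diagnostic plots: the R^2 matching profile (`ion_match`), the
#' estimated-versus-true accuracy line (`ion_calibration`), confidence
#' half-width versus array size (`ion_redundancy`), the confusion-matrix
#' heatmap (`ion_task`), PCA scores (`ion_pca`) and the sensitivity fit
#' (`ion_sensitivity`).
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-ionarray
NULL

#' @rdname autoplot-ionarray
#' @export
autoplot.ion_match <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(.data$v_gs_V, .data$r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$v_star, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "calibration slice V_GS (V)", y = expression(R^2),
                  title = sprintf("profile match: v* = %+.3f V", object$v_star)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-ionarray
#' @export
autoplot.ion_calibration <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
    ggplot2::aes(log10(.data$c_est_mol_per_L),
                 log10(.data$conc_mol_per_L))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", colour = "red") +
    ggplot2::geom_point(shape = 15) +
    ggplot2::labs(x = "log10(estimated conc, mol/L)",
                  y = "log10(true conc, mol/L)",
                  title = sprintf("slope %.3f, R^2 %.3f", object$slope,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-ionarray
#' @export
autoplot.ion_redundancy <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
    ggplot2::aes(.data$n_devices, .data$half_width_pct)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "devices sampled",
                  y = "95% CI half-width (% of true conc)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-ionarray
#' @export
autoplot.ion_task <- function(object, ...) {
  df <- tidy.ion_task(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$prediction, .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(title = sprintf("%s: accuracy %.3f", object$task,
                                  object$accuracy_mean)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-ionarray
#' @export
autoplot.ion_pca <- function(object, ...) {
  sc <- object$scores
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2))
  if ("label" %in% names(sc))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$label))
  else p <- p + ggplot2::geom_point()
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * object$variance_fraction[1]),
    y = sprintf("PC2 (%.1f%%)", 100 * object$variance_fraction[2])) +
    ggplot2::theme_minimal()
}
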