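#' ECDF-based synthetic device responses
#'
#' Expands a measured device population into an arbitrarily large synthetic
#' one by inverse-transform sampling from the per-gate-voltage empirical
#' cumulative distribution functions of the measured currents. One uniform
#' rank `u` is drawn per synthetic device and used to invert the ECDF of
#' every (solution, gate-voltage) column with that same `u` (comonotonic
#' coupling), so each synthetic device keeps a coherent curve shape: a
#' device that sits at the 90th percentile of current at one gate voltage
#' sits there at every gate voltage. Marginal distributions converge to the
#' source ECDFs as the synthetic population grows.
#'
#' @param measured Long-format measurement tibble from [run_panel()] (or
#'   read back via [read_measurement()]); all (solution, v_gs) columns of
#'   the same devices are synthesized jointly.
#' @param n_synthetic Number of synthetic devices to generate.
#' @param u Optional vector of ranks in (0, 1), length `n_synthetic`,
#'   overriding the uniform draw (e.g. `u = 0.5` forces the per-voltage
#'   median curve); recycled.
#' @param seed Optional integer seed.
#' @return An object of class `ion_population`: a list with `values`
#'   (matrix, synthetic devices x measurement columns), `columns` (tibble
#'   of `solution`, `v_gs_V`), `u`, and `n_source`. Use
#'   [as_tibble()][tibble::as_tibble] to get back a long measurement table.
#' @export
ecdf_synthesize <- function(measured, n_synthetic, u = NULL, seed = NULL) {
  wide <- measurement_matrix(measured)
  m <- nrow(wide$values)
  if (m < 2) abort("need at least 2 source devices to form an ECDF.")
  if (m < 10)
    warning("fewer than 10 source devices; synthetic curves will be coarse.")
  u <- with_seed_or_not(seed, {
    if (is.null(u)) runif(n_synthetic) else rep_len(u, n_synthetic)
  })
  if (any(u <= 0 | u > 1)) abort("`u` must lie in (0, 1].")
  ranks <- pmin(pmax(ceiling(u * m), 1L), m)  # type-1 inverse ECDF
  sorted <- apply(wide$values, 2, sort)
  values <- sorted[ranks, , drop = FALSE]
  rownames(values) <- NULL
  structure(
    list(values = values, columns = wide$columns, u = u, n_source = m,
         v_ds_V = wide$v_ds_V),
    class = "ion_population"
  )
}

# Pivot a long measurement to a devices x (solution, v_gs) matrix with a
# stable device ordering (row, col).
measurement_matrix <- function(measured, direction = NULL) {
  need <- c("row", "col", "solution", "v_gs_V", "i_ds_A")
  if (!all(need %in% names(measured)))
    abort(paste("measurement must have columns:", paste(need, collapse = ", ")))
  if (!is.null(direction) && "direction" %in% names(measured))
    measured <- measured[measured$direction == direction, ]
  measured <- dplyr::arrange(measured, .data$solution, .data$v_gs_V,
                             .data$row, .data$col)
  key <- paste(measured$solution, format(measured$v_gs_V, digits = 15))
  cols <- !duplicated(key)
  columns <- tibble::tibble(solution = measured$solution[cols],
                            v_gs_V = measured$v_gs_V[cols])
  dev <- dplyr::distinct(dplyr::arrange(measured, .data$row, .data$col),
                         .data$row, .data$col)
  n_dev <- nrow(dev); n_col <- nrow(columns)
  if (nrow(measured) != n_dev * n_col)
    abort("measurement is not a complete device x (solution, v_gs) grid.")
  ord <- order(match(key, key[cols]),
               match(paste(measured$row, measured$col),
                     paste(dev$row, dev$col)))
  values <- matrix(measured$i_ds_A[ord], nrow = n_dev, ncol = n_col)
  list(values = values, columns = columns, devices = dev,
       v_ds_V = if ("v_ds_V" %in% names(measured)) measured$v_ds_V[1] else NA_real_)
}

#' @export
print.ion_population <- function(x, ...) {
  cat(sprintf("<ion_population> %d synthetic devices x %d measurement columns (from %d source devices)\n",
              nrow(x$values), ncol(x$values), x$n_source))
  cat("  solutions:", paste(unique(x$columns$solution), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as_tibble.ion_population <- function(x, ...) {
  n <- nrow(x$values)
  k <- ncol(x$values)
  tibble::tibble(
    chip_id = "synthetic", row = rep(seq_len(n), times = k), col = 0L,
    ism = NA_character_,
    solution = rep(x$columns$solution, each = n),
    direction = "forward",
    v_ds_V = x$v_ds_V,
    v_gs_V = rep(x$columns$v_gs_V, each = n),
    i_ds_A = as.vector(x$values)
  )
}

#' Extract a current slice at one gate voltage
#'
#' A current slice is the vector of per-device drain currents at one fixed
#' gate voltage in one solution -- the object the profile-matching
#' calibration correlates across devices.
#'
#' @param x A long measurement tibble or an `ion_population`.
#' @param solution Solution label to slice.
#' @param v_gs Gate voltage of the slice (V); snapped to the nearest grid
#'   point.
#' @param direction Sweep direction to use when present.
#' @return Tibble with columns `row`, `col`, `i_ds_A` (class
#'   `current_slice`), with attributes `v_gs_V` and `solution`.
#' @export
current_slice <- function(x, solution, v_gs = 0, direction = "forward") {
  UseMethod("current_slice")
}

#' @export
current_slice.data.frame <- function(x, solution, v_gs = 0,
                                     direction = "forward") {
  sub <- x[x$solution == solution, ]
  if ("direction" %in% names(sub)) sub <- sub[sub$direction == direction, ]
  if (!nrow(sub)) abort(paste0("no measurements for solution '", solution, "'."))
  grid <- sort(unique(sub$v_gs_V))
  v0 <- grid[which.min(abs(grid - v_gs))]
  sub <- dplyr::arrange(sub[sub$v_gs_V == v0, ], .data$row, .data$col)
  out <- tibble::tibble(row = sub$row, col = sub$col, i_ds_A = sub$i_ds_A)
  attr(out, "v_gs_V") <- v0
  attr(out, "solution") <- solution
  class(out) <- c("current_slice", class(out))
  out
}

#' @export
current_slice.ion_population <- function(x, solution, v_gs = 0,
                                         direction = "forward") {
  sel <- which(x$columns$solution == solution)
  if (!length(sel)) abort(paste0("no columns for solution '", solution, "'."))
  j <- sel[which.min(abs(x$columns$v_gs_V[sel] - v_gs))]
  out <- tibble::tibble(row = seq_len(nrow(x$values)), col = 0L,
                        i_ds_A = x$values[, j])
  attr(out, "v_gs_V") <- x$columns$v_gs_V[j]
  attr(out, "solution") <- solution
  class(out) <- c("current_slice", class(out))
  out
}
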