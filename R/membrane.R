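#' Ion-selective membrane specification
#'
#' Describes one ion-selective membrane (ISM): the target ion and its
#' valence, cross-sensitivity to interfering ions (Nikolsky-Eisenman
#' selectivity coefficients), the transient response-time constant, and the
#' Dirac-voltage shift the functionalization layer imprints on the graphene
#' channel (the K+ and Ca2+ ionophore cocktails p-dope the channel strongly,
#' the Na+ one is nearly neutral).
#'
#' @param target_ion Species label, e.g. `"K"`, `"Na"`, `"Ca"`.
#' @param z Integer valence of the target ion, 1 or 2.
#' @param selectivity Named numeric vector of selectivity coefficients
#'   \eqn{K_{ij} \ge 0} for interfering species; the coefficient of the
#'   target species itself is fixed at 1 by convention.
#' @param tau_s Response time constant in seconds (> 0). The 90% response
#'   time of an exponential step is `tau_s * log(10)`.
#' @param doping_offset_V Shift (V) added to the intrinsic device Dirac
#'   voltage by the functionalization layer.
#' @return An object of class `membrane_spec`.
#' @seealso [ism_library()] for the three stock membranes.
#' @export
membrane_spec <- function(target_ion, z, selectivity = numeric(),
                          tau_s = 2.5, doping_offset_V = 0) {
  stopifnot(is.character(target_ion), length(target_ion) == 1L)
  if (!z %in% c(1L, 2L)) abort("`z` must be 1 or 2.")
  if (length(selectivity) && is.null(names(selectivity)))
    abort("`selectivity` must be a named numeric vector.")
  if (any(selectivity < 0)) abort("selectivity coefficients must be >= 0.")
  if (!is.numeric(tau_s) || tau_s <= 0) abort("`tau_s` must be > 0.")
  selectivity <- selectivity[names(selectivity) != target_ion]
  structure(
    list(target_ion = target_ion, z = as.integer(z),
         selectivity = selectivity, tau_s = tau_s,
         doping_offset_V = doping_offset_V),
    class = "membrane_spec"
  )
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf("<membrane_spec> %s (z = %d), tau_s = %.3g s, doping offset = %+.3g V\n",
              x$target_ion, x$z, x$tau_s, x$doping_offset_V))
  if (length(x$selectivity))
    cat("  selectivity:",
        paste(sprintf("%s = %g", names(x$selectivity), x$selectivity),
              collapse = ", "), "\n")
  invisible(x)
}

#' Stock ion-selective membranes
#'
#' The three membranes used throughout: valinomycin-type K+, ionophore-X-type
#' Na+ and ETH-129-type Ca2+. Response-time constants are set so the
#' population-mean 90% response times are 7.4 s (K+), 5.9 s (Na+) and
#' 5.1 s (Ca2+). Selectivity defaults are small but non-zero (0.01 between
#' the monovalent pair, 0.005 across valences) so that cross-ISM information
#' exists in multiplexed data. K+ and Ca2+ membranes p-dope the channel
#' (positive Dirac shift); the Na+ membrane is close to neutral.
#'
#' @return Named list of [membrane_spec()] objects (`K`, `Na`, `Ca`).
#' @export
ism_library <- function() {
  list(
    K = membrane_spec("K", 1L, c(Na = 0.01, Ca = 0.005),
                      tau_s = 7.4 / log(10), doping_offset_V = 0.25),
    Na = membrane_spec("Na", 1L, c(K = 0.01, Ca = 0.005),
                       tau_s = 5.9 / log(10), doping_offset_V = 0.03),
    Ca = membrane_spec("Ca", 2L, c(K = 0.005, Na = 0.005),
                       tau_s = 5.1 / log(10), doping_offset_V = 0.20)
  )
}

#' Electrolyte solution specification
#'
#' @param concentrations Named numeric vector of molar concentrations
#'   (mol/L, >= 0), one entry per ionic species, e.g. `c(Ca = 1e-3)`.
#' @param temperature_K Absolute temperature (K), default 298.15.
#' @param label Identifier used as the `solution` key in measurement tables;
#'   autogenerated from the composition when omitted.
#' @return An object of class `solution_spec`.
#' @export
solution_spec <- function(concentrations, temperature_K = 298.15,
                          label = NULL) {
  if (is.null(names(concentrations)) || !is.numeric(concentrations))
    abort("`concentrations` must be a named numeric vector (mol/L).")
  if (any(concentrations < 0)) abort("concentrations must be >= 0.")
  if (temperature_K <= 0) abort("`temperature_K` must be > 0.")
  label <- label %||%
    paste(sprintf("%s_%s", names(concentrations),
                  conc_label(concentrations)), collapse = "+")
  structure(
    list(concentrations = concentrations, temperature_K = temperature_K,
         label = label),
    class = "solution_spec"
  )
}

#' @export
print.solution_spec <- function(x, ...) {
  cat(sprintf("<solution_spec> %s @ %.2f K: %s\n", x$label, x$temperature_K,
              paste(sprintf("%s = %g mol/L", names(x$concentrations),
                            x$concentrations), collapse = ", ")))
  invisible(x)
}

# Human-readable concentration label: 1e-3 -> "1mM", 1e-5 -> "10uM"
conc_label <- function(c_mol) {
  vapply(c_mol, function(ci) {
    if (ci == 0) return("0")
    if (ci >= 1e-3) paste0(format(ci * 1e3, trim = TRUE, drop0trailing = TRUE), "mM")
    else paste0(format(ci * 1e6, trim = TRUE, drop0trailing = TRUE), "uM")
  }, character(1))
}

#' Pure-solution measurement panel
#'
#' The standard characterization panel: for each ion, five decade-spaced
#' single-analyte dilutions (10 uM, 100 uM, 1 mM, 10 mM, 100 mM), i.e.
#' 15 solutions for the three stock ions.
#'
#' @param ions Character vector of species labels.
#' @param concentrations Molar concentrations per ion.
#' @param temperature_K Temperature (K).
#' @return List of [solution_spec()] objects.
#' @export
pure_solution_panel <- function(ions = c("K", "Na", "Ca"),
                                concentrations = 10^(-5:-1),
                                temperature_K = 298.15) {
  specs <- list()
  for (ion in ions)
    for (ci in concentrations)
      specs[[length(specs) + 1L]] <-
        solution_spec(setNames(ci, ion), temperature_K)
  specs
}

#' Mixture-solution panel
#'
#' Multi-ion solutions drawn from the full factorial over the three stock
#' ions at levels 0, 0.1, 1, 10 and 100 mM (the all-zero point excluded),
#' subsampled to `n` solutions. The subsample is redrawn (deterministically
#' under `seed`) until every ion sees every level at least `min_per_level`
#' times, so concentration classes stay populated for learning tasks.
#'
#' @param n Number of mixture solutions (<= 124).
#' @param levels Per-ion concentration levels (mol/L), including 0.
#' @param ions Species labels.
#' @param min_per_level Minimum occurrences of each (ion, level) pair.
#' @param seed Optional integer seed.
#' @param temperature_K Temperature (K).
#' @return List of [solution_spec()] objects.
#' @export
mixture_solution_panel <- function(n = 30, levels = c(0, 10^(-4:-1)),
                                   ions = c("K", "Na", "Ca"),
                                   min_per_level = 2, seed = NULL,
                                   temperature_K = 298.15) {
  grid <- expand.grid(rep(list(levels), length(ions)))
  names(grid) <- ions
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  if (n > nrow(grid)) abort("`n` exceeds the factorial design size.")
  with_seed_or_not(seed, {
    for (attempt in seq_len(1000L)) {
      idx <- sample.int(nrow(grid), n)
      sub <- grid[idx, , drop = FALSE]
      ok <- all(vapply(ions, function(ion)
        all(table(factor(sub[[ion]], levels = levels)) >= min_per_level),
        logical(1)))
      if (ok) break
    }
    if (!ok) abort("could not cover all (ion, level) pairs; increase `n`.")
    lapply(seq_len(nrow(sub)), function(i)
      solution_spec(setNames(as.numeric(sub[i, ]), ions),
                    temperature_K = temperature_K))
  })
}

#' Tabulate solution metadata
#'
#' Long-format solution metadata, the on-disk companion of a measurement
#' table (columns `solution`, `species`, `conc_mol_per_L`, `temperature_K`).
#'
#' @param solutions List of [solution_spec()] objects.
#' @return A tibble.
#' @export
solutions_table <- function(solutions) {
  if (inherits(solutions, "solution_spec")) solutions <- list(solutions)
  purrr::map_dfr(solutions, function(s)
    tibble::tibble(solution = s$label,
                   species = names(s$concentrations),
                   conc_mol_per_L = unname(s$concentrations),
                   temperature_K = s$temperature_K))
}

#' Rebuild solution specs from a metadata table
#'
#' @param tbl A tibble as produced by [solutions_table()].
#' @return List of [solution_spec()] objects, in first-appearance order.
#' @export
solutions_from_table <- function(tbl) {
  stopifnot(all(c("solution", "species", "conc_mol_per_L") %in% names(tbl)))
  labs <- unique(tbl$solution)
  lapply(labs, function(lab) {
    sub <- tbl[tbl$solution == lab, ]
    temp <- if ("temperature_K" %in% names(sub)) sub$temperature_K[1] else 298.15
    solution_spec(setNames(sub$conc_mol_per_L, sub$species),
                  temperature_K = temp, label = lab)
  })
}

#' Membrane potential of an ISM in a solution
#'
#' Potential developed at the electrolyte/membrane interface, relative to a
#' reference concentration `c_ref` of the target ion:
#' \deqn{V_M = \frac{\ln 10 \, R T}{z F} \log_{10}\!\frac{a_{\mathrm{eff}}}{c_{\mathrm{ref}}}}
#' with the Nikolsky-Eisenman effective activity
#' \eqn{a_{\mathrm{eff}} = c_i + \sum_j K_{ij} c_j^{z_i/z_j}} summing over
#' interfering species. Activities are taken equal to concentrations
#' (ideal-solution assumption). Strictly increasing in the target-ion
#' concentration.
#'
#' @param membrane A [membrane_spec()].
#' @param solution A [solution_spec()].
#' @param c_ref Reference molar concentration (> 0).
#' @param z_of Named integer vector giving the valence of possible
#'   interfering species (used for the \eqn{z_i/z_j} exponents).
#' @return Membrane potential in volts.
#' @export
membrane_potential <- function(membrane, solution, c_ref,
                               z_of = c(K = 1, Na = 1, Ca = 2)) {
  stopifnot(inherits(membrane, "membrane_spec"),
            inherits(solution, "solution_spec"))
  if (!is.numeric(c_ref) || c_ref <= 0) abort("`c_ref` must be > 0.")
  conc <- solution$concentrations
  a_eff <- conc[membrane$target_ion]
  if (is.na(a_eff)) a_eff <- 0
  zi <- membrane$z
  for (sp in names(membrane$selectivity)) {
    cj <- conc[sp]
    if (is.na(cj) || cj == 0) next
    zj <- z_of[sp]
    if (is.na(zj)) zj <- 1
    a_eff <- a_eff + membrane$selectivity[[sp]] * cj^(zi / zj)
  }
  if (a_eff <= 0)
    abort("effective activity is non-positive; membrane potential undefined.")
  nernst_slope(zi, solution$temperature_K) * log10(unname(a_eff) / c_ref)
}
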