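#' Physical parameters of one graphene EGFET
#'
#' Compact-model parameters of a single electrolyte-gated graphene
#' field-effect transistor. The channel is a resistor network: two contact
#' resistances in series with a gate-dependent sheet resistance whose
#' carrier density follows the usual symmetric form
#' \eqn{n_s = \sqrt{n_0^2 + (C_{edl} \Delta V / q)^2}}, giving the V-shaped
#' transfer characteristic with its minimum at the Dirac voltage.
#'
#' @param V_dirac0 Intrinsic (pre-functionalization) Dirac voltage (V).
#' @param mu Carrier mobility (m^2 V^-1 s^-1, > 0).
#' @param R_c Total (two-contact) contact resistance (Ohm, >= 0).
#' @param n0 Residual carrier sheet density at the Dirac point (m^-2, > 0).
#' @param C_edl Electrolyte double-layer gate capacitance per area
#'   (F m^-2, > 0).
#' @param W,L Channel width and length (m, > 0).
#' @param sens_scale Per-device multiplier on the Nernst slope
#'   (dimensionless, > 0, population mean near 1; values above 1 describe
#'   super-Nernstian devices).
#' @param functional Working-device flag.
#' @return An object of class `device_params`.
#' @export
device_params <- function(V_dirac0 = 0.15, mu = 0.1, R_c = 1000,
                          n0 = 5e15, C_edl = 0.02, W = 30e-6, L = 30e-6,
                          sens_scale = 1, functional = TRUE) {
  if (mu <= 0 || n0 <= 0 || C_edl <= 0 || W <= 0 || L <= 0 || sens_scale <= 0)
    abort("mu, n0, C_edl, W, L and sens_scale must all be > 0.")
  if (R_c < 0) abort("`R_c` must be >= 0.")
  structure(
    list(V_dirac0 = V_dirac0, mu = mu, R_c = R_c, n0 = n0, C_edl = C_edl,
         W = W, L = L, sens_scale = sens_scale,
         functional = isTRUE(functional)),
    class = "device_params"
  )
}

#' @export
print.device_params <- function(x, ...) {
  cat(sprintf(paste0("<device_params> V_dirac0 = %.3f V, mu = %.3g m2/Vs, ",
                     "R_c = %.3g Ohm, n0 = %.3g m-2, C_edl = %.3g F/m2, ",
                     "W/L = %.3g, sens_scale = %.3f%s\n"),
              x$V_dirac0, x$mu, x$R_c, x$n0, x$C_edl, x$W / x$L,
              x$sens_scale, if (x$functional) "" else " (non-functional)"))
  invisible(x)
}

# Core compact model, vectorized over v_gs (and any parameter of equal
# length). v_dirac_eff already includes membrane doping and the membrane
# potential: the current minimum sits at v_gs == v_dirac_eff.
egfet_current <- function(v_gs, v_ds, v_dirac_eff, mu, R_c, n0, C_edl, W, L) {
  n_s <- sqrt(n0^2 + (C_edl * (v_gs - v_dirac_eff) / .Q_E)^2)
  v_ds / (2 * R_c + (L / W) / (.Q_E * mu * n_s))
}

#' Simulate one transfer (I-V) curve
#'
#' Steady-state drain current versus gate voltage of a membrane-covered
#' device in a given solution. The membrane potential adds in series with
#' the applied gate voltage, so increasing target-cation concentration
#' shifts the whole curve left along the gate-voltage axis by
#' `sens_scale * V_M` (a pure translation in this model); the
#' functionalization doping offset shifts the Dirac voltage.
#'
#' @param device A [device_params()].
#' @param membrane A [membrane_spec()], or `NULL` for a bare channel.
#' @param solution A [solution_spec()].
#' @param c_ref Reference molar concentration for the membrane potential.
#' @param v_gs Monotone increasing gate-voltage grid (V), length >= 3. The
#'   default is the standard sweep, -0.6 to 0.9 V in 10 mV steps (151 pts).
#' @param v_ds Drain bias (V).
#' @param noise_rel Relative s.d. of multiplicative Gaussian current noise.
#' @param seed Optional seed for the noise draw.
#' @return Tibble with columns `v_gs_V`, `i_ds_A`; attributes `v_ds_V` and
#'   `solution`.
#' @export
simulate_iv <- function(device, membrane, solution, c_ref = 1e-3,
                        v_gs = seq(-0.6, 0.9, by = 0.01), v_ds = 0.3,
                        noise_rel = 0, seed = NULL) {
  stopifnot(inherits(device, "device_params"))
  if (length(v_gs) < 3 || any(diff(v_gs) <= 0))
    abort("`v_gs` must be strictly increasing with length >= 3.")
  if (!is.finite(v_ds)) abort("`v_ds` must be finite.")
  v_m <- 0
  doping <- 0
  if (!is.null(membrane)) {
    v_m <- membrane_potential(membrane, solution, c_ref)
    doping <- membrane$doping_offset_V
  }
  v_dirac_eff <- device$V_dirac0 + doping - device$sens_scale * v_m
  i <- egfet_current(v_gs, v_ds, v_dirac_eff, device$mu, device$R_c,
                     device$n0, device$C_edl, device$W, device$L)
  if (noise_rel > 0)
    i <- with_seed_or_not(seed,
      i * (1 + rnorm(length(i), sd = noise_rel)))
  out <- tibble::tibble(v_gs_V = as.numeric(v_gs), i_ds_A = i)
  attr(out, "v_ds_V") <- v_ds
  attr(out, "solution") <- if (inherits(solution, "solution_spec"))
    solution$label else NA_character_
  out
}

#' Simulate a transient current trace across a solution sequence
#'
#' The device sits at a fixed gate and drain bias while the chip is moved
#' through a sequence of solutions. Within each dwell the current relaxes
#' exponentially from its previous value toward the steady-state
#' [simulate_iv()] current with the membrane's time constant `tau_s`, so the
#' 90% response time of a single step is `tau_s * log(10)`. With the gate
#' biased on the hole branch, conductance falls when the cation
#' concentration rises.
#'
#' @param device A [device_params()].
#' @param membrane A [membrane_spec()].
#' @param solutions List of [solution_spec()], in exposure order.
#' @param dwell_s Dwell time per solution (seconds), scalar or vector.
#' @param c_ref Reference molar concentration.
#' @param v_gs_fixed Fixed gate voltage (V).
#' @param v_ds Drain bias (V).
#' @param dt Sample interval (s), 0 < dt <= min(dwell_s).
#' @param noise_rel Relative s.d. of per-sample multiplicative noise.
#' @param tau_s Override of the membrane time constant (s); defaults to
#'   `membrane$tau_s`. `tau_s = 0` gives an instantaneous response.
#' @param i_init Starting current (A); default is the steady state of the
#'   first solution.
#' @param seed Optional seed for the noise draw.
#' @return Tibble with columns `time_s`, `i_ds_A`, `solution`.
#' @export
simulate_transient <- function(device, membrane, solutions, dwell_s,
                               c_ref = 1e-3, v_gs_fixed = -0.1, v_ds = 0.3,
                               dt = 0.1, noise_rel = 0, tau_s = NULL,
                               i_init = NULL, seed = NULL) {
  if (inherits(solutions, "solution_spec")) solutions <- list(solutions)
  if (!length(solutions)) abort("`solutions` must be a non-empty list.")
  dwell_s <- rep_len(dwell_s, length(solutions))
  if (dt <= 0 || any(dwell_s < dt)) abort("need dwell_s >= dt > 0.")
  if (noise_rel < 0) abort("`noise_rel` must be >= 0.")
  tau <- tau_s %||% membrane$tau_s
  i_ss <- vapply(solutions, function(s) {
    grid <- v_gs_fixed + c(-0.01, 0, 0.01)
    simulate_iv(device, membrane, s, c_ref, v_gs = grid, v_ds = v_ds)$i_ds_A[2]
  }, numeric(1))
  times <- list(); currents <- list(); labels <- list()
  t0 <- 0
  i_prev <- i_init %||% i_ss[1]
  for (k in seq_along(solutions)) {
    tk <- seq(dt, dwell_s[k], by = dt)
    decay <- if (tau > 0) exp(-tk / tau) else rep(0, length(tk))
    ik <- i_ss[k] + (i_prev - i_ss[k]) * decay
    times[[k]] <- t0 + tk
    currents[[k]] <- ik
    labels[[k]] <- rep(solutions[[k]]$label, length(tk))
    t0 <- t0 + dwell_s[k]
    i_prev <- ik[length(ik)]
  }
  i_all <- unlist(currents)
  if (noise_rel > 0)
    i_all <- with_seed_or_not(seed,
      i_all * (1 + rnorm(length(i_all), sd = noise_rel)))
  tibble::tibble(time_s = unlist(times), i_ds_A = i_all,
                 solution = unlist(labels))
}
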