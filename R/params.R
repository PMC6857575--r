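#' Ring-network parameters
#'
#' Container for the constants of the recurrent orientation-ring model.
#' The defaults are the published set obtained by fitting the network's
#' adaptation-induced tuning-curve shifts to macaque V1 recordings; they
#' were calibrated with 256 units, and [simulate_ring()] emits a message
#' if `n_units` is changed while the remaining constants are left at
#' their defaults.
#'
#' @param tau Membrane time constant, ms.
#' @param alpha Rate gain, Hz per mV of suprathreshold potential.
#' @param j_lgn Strength of the feedforward (LGN) drive, mV.
#' @param kappa_lgn Concentration of the feedforward orientation tuning
#'   (dimensionless; larger = sharper).
#' @param j_cortex Strength of the recurrent cortical connections,
#'   mV per Hz.
#' @param r_ie Ratio of inhibitory to excitatory recurrent strength.
#' @param kappa_e,kappa_i Concentrations of the excitatory and
#'   inhibitory recurrent profiles; `kappa_e > kappa_i` gives the
#'   Mexican-hat shape (narrow excitation, broad inhibition).
#' @param n_units Number of model neurons, evenly tiling `[0, 180)`
#'   degrees of preferred orientation.  Must be at least 8.
#'
#' @return An object of class `network_params` (a named list).
#' @examples
#' p <- network_params()
#' p$tau
#' @export
network_params <- function(tau = 8, alpha = 3.88,
                           j_lgn = 11.04, kappa_lgn = 0.47,
                           j_cortex = 2.84, r_ie = 1.24,
                           kappa_e = 1.12, kappa_i = 0.56,
                           n_units = 256L) {
  p <- list(tau = tau, alpha = alpha, j_lgn = j_lgn, kappa_lgn = kappa_lgn,
            j_cortex = j_cortex, r_ie = r_ie, kappa_e = kappa_e,
            kappa_i = kappa_i, n_units = as.integer(n_units))
  num <- p[setdiff(names(p), "n_units")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1 &&
                    is.finite(v) && v > 0, logical(1)))) {
    stop_domain("All network constants must be single strictly positive numbers.")
  }
  if (p$n_units < 8) {
    stop_domain("`n_units` must be at least 8; fewer units make the connection profile and decoder meaningless.")
  }
  structure(p, class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params>", x$n_units, "units\n")
  cat(sprintf("  tau = %g ms, alpha = %g Hz/mV\n", x$tau, x$alpha))
  cat(sprintf("  LGN: j = %g, kappa = %g\n", x$j_lgn, x$kappa_lgn))
  cat(sprintf("  cortex: j = %g, r_IE = %g, kappa_E = %g, kappa_I = %g\n",
              x$j_cortex, x$r_ie, x$kappa_e, x$kappa_i))
  invisible(x)
}

# Preferred orientations: i * 180 / n, i = 0 .. n-1 (no duplicated endpoint).
preferred_orientations <- function(n_units) {
  (seq_len(n_units) - 1) * 180 / n_units
}

is_default_constants <- function(p) {
  d <- network_params()
  keys <- setdiff(names(d), "n_units")
  all(vapply(keys, function(k) isTRUE(all.equal(p[[k]], d[[k]])), logical(1)))
}

#' Numerical-integration settings
#'
#' The network ODE is integrated with an adaptive Dormand-Prince
#' Runge-Kutta scheme (the classic `ode45` pairing) and the solution is
#' reported on a regular output grid.
#'
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param dt_out Output grid step, ms.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(rtol = 1e-6, atol = 1e-9, dt_out = 1) {
  if (rtol <= 0 || atol <= 0 || dt_out <= 0) {
    stop_domain("Solver tolerances and the output step must be positive.")
  }
  structure(list(rtol = rtol, atol = atol, dt_out = dt_out),
            class = "solver_settings")
}
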