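#' Orientation-domain von Mises density
#'
#' Circular analogue of a Gaussian with period 180 degrees, the natural
#' tuning-curve shape on the orientation domain:
#' `f(x | mu, kappa) = exp(kappa * cos(2 * (x - mu))) / (2 * pi * I0(kappa))`
#' with angles in radians internally and `I0` the modified Bessel
#' function of order zero.  `kappa = 0` gives the uniform circular
#' density `1 / (2 * pi)`.
#'
#' @param x Orientation(s), degrees.
#' @param mu Mean orientation, degrees.
#' @param kappa Concentration, dimensionless, `>= 0`.
#' @return Density values, same length as `x` (recycled against `mu`).
#' @examples
#' von_mises_density(0, 0, 1)
#' von_mises_density(20, 20 + 180, 2) == von_mises_density(20, 20, 2)
#' @export
von_mises_density <- function(x, mu, kappa) {
  if (!is.numeric(kappa) || any(kappa < 0) || any(!is.finite(kappa))) {
    stop_domain("`kappa` must be finite and non-negative.")
  }
  exp(kappa * cos(2 * (x - mu) * pi / 180)) / (2 * pi * besselI(kappa, 0))
}

#' Feedforward (LGN) drive to a ring unit
#'
#' The weakly tuned thalamic input: a von Mises profile of the stimulus
#' orientation centred on the unit's preferred orientation, scaled by
#' contrast, `V = c * j_lgn * f(omega | theta, kappa_lgn)`.
#'
#' @param theta Unit preferred orientation(s), degrees.
#' @param omega Stimulus orientation, degrees.
#' @param contrast Stimulus contrast, `>= 0` (dimensionless).
#' @param params A [network_params()] object.
#' @return Synaptic potential(s), mV.
#' @export
lgn_drive <- function(theta, omega, contrast, params = network_params()) {
  if (any(contrast < 0)) stop_domain("`contrast` must be non-negative.")
  contrast * params$j_lgn * von_mises_density(theta, omega, params$kappa_lgn)
}

#' Recurrent connection profile
#'
#' Mexican-hat synaptic weight from a unit preferring `phi` onto a unit
#' preferring `theta`, as a difference of a narrow excitatory and a
#' broad inhibitory von Mises profile:
#' `F(phi - theta) = j_cortex * (f(phi | theta, kappa_e) - r_ie * f(phi | theta, kappa_i))`.
#' Depends only on the circular difference (period 180 degrees) and is
#' even in it.
#'
#' @param phi_minus_theta Circular difference of preferred orientations,
#'   degrees.
#' @param params A [network_params()] object.
#' @return Synaptic weight(s), mV per Hz.
#' @export
connection_profile <- function(phi_minus_theta, params = network_params()) {
  params$j_cortex * (von_mises_density(phi_minus_theta, 0, params$kappa_e) -
                       params$r_ie * von_mises_density(phi_minus_theta, 0, params$kappa_i))
}

# n x n recurrent weight matrix, including the orientation-space measure
# d_phi = pi / n so the recurrent input is the discretized integral
# of F(phi) R(phi) over the half-circle.  This keeps the effective
# coupling independent of n_units.
connection_matrix <- function(params) {
  th <- preferred_orientations(params$n_units)
  (pi / params$n_units) * connection_profile(outer(th, th, "-"), params)
}
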