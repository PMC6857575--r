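#' Rate-suppression parameters and presets
#'
#' Adaptation-induced firing-rate suppression: after the adapter turns
#' off at `t0`, each unit's rate is reduced by an amount proportional
#' (gain `beta`) to its own mean rate during the adaptation window,
#' recovering exponentially with time constant `rho`:
#' `R_adapt(t) = R(t) - beta * <R> * exp(-(t - t0) / rho)`, clipped at
#' zero.  Suppression acts on the readout rates only; it is not fed
#' back into the recurrent input.
#'
#' Presets bundle the two regimes estimated from macaque V1: `"weak"`
#' (`beta = 0.20`, `rho = 100` ms; brief, sub-second adapters) and
#' `"strong"` (`beta = 0.50`, `rho = 500` ms; adapters of seconds),
#' plus `"none"` (`beta = 0`).
#'
#' @param beta Suppression gain, fraction of the mean adapter rate, in
#'   `[0, 1]`.
#' @param rho Recovery time constant, ms, `> 0`.
#' @param t0 Adapter offset time, ms; suppression applies for
#'   `t >= t0`.
#' @param window Adaptation window `[start, end]` (ms) over which the
#'   per-unit mean rate is taken; its end must equal `t0`.
#' @return An object of class `suppression_params`.
#' @examples
#' suppression_preset("strong", t0 = 200)
#' @export
suppression_params <- function(beta, rho, t0, window = c(0, t0)) {
  if (beta < 0 || beta > 1) stop_domain("`beta` must lie in [0, 1].")
  if (rho <= 0) stop_domain("`rho` must be positive.")
  if (length(window) != 2 || window[2] <= window[1]) {
    stop_domain("`window` must be an increasing [start, end] pair.")
  }
  if (!isTRUE(all.equal(window[2], t0))) {
    stop_domain("The adaptation window must end at the adapter offset `t0`.")
  }
  structure(list(beta = beta, rho = rho, t0 = t0, window = window),
            class = "suppression_params")
}

#' @rdname suppression_params
#' @param variant Preset name: `"none"`, `"weak"` or `"strong"`.
#' @export
suppression_preset <- function(variant = c("none", "weak", "strong"), t0,
                               window = c(0, t0)) {
  variant <- match.arg(variant)
  br <- switch(variant, none = c(0, 100), weak = c(0.20, 100),
               strong = c(0.50, 500))
  p <- suppression_params(br[1], br[2], t0, window)
  p$variant <- variant
  p
}

#' Per-unit mean firing rate over the adaptation window
#'
#' Time-average of each unit's rate over the grid samples falling in
#' `[start, end)` — the drive of the suppression term.
#'
#' @param traj A `ring_trajectory`.
#' @param window `[start, end]` in ms, within the trajectory's time
#'   range.
#' @return Named-free numeric vector, one mean rate (Hz) per unit.
#' @export
mean_adapter_rate <- function(traj, window) {
  if (length(window) != 2 || window[2] <= window[1]) {
    stop_domain("`window` must be an increasing [start, end] pair.")
  }
  sel <- traj$times >= window[1] & traj$times < window[2]
  if (!any(sel)) stop_domain("No trajectory samples fall inside the adaptation window.")
  colMeans(traj$rates[sel, , drop = FALSE])
}

#' Apply rate suppression to a trajectory
#'
#' @param traj A `ring_trajectory`.
#' @param mean_rates Per-unit mean adapter rates (Hz), e.g. from
#'   [mean_adapter_rate()].
#' @param p A [suppression_params()] object.
#' @return A `ring_trajectory` with rates unchanged for `t < t0` and
#'   suppressed (and clipped at zero) for `t >= t0`.  Voltages are
#'   dropped: the suppressed rates are no longer the rectified-linear
#'   image of the membrane potential.
#' @export
apply_suppression <- function(traj, mean_rates, p) {
  stopifnot(inherits(p, "suppression_params"))
  if (length(mean_rates) != length(traj$preferred)) {
    stop_domain("`mean_rates` must hold one value per unit.")
  }
  post <- traj$times >= p$t0
  if (!any(post)) stop_domain("No trajectory samples at or after `t0`.")
  out <- traj
  if (p$beta > 0) {
    decay <- exp(-(traj$times[post] - p$t0) / p$rho)
    out$rates[post, ] <- pmax(0, traj$rates[post, , drop = FALSE] -
                                   outer(decay, p$beta * mean_rates))
  }
  out$voltages <- NULL
  out$suppression <- p
  out
}

#' Simulate-and-suppress convenience wrapper
#'
#' Computes the mean adapter rate over `p$window` and applies the
#' suppression in one call.
#'
#' @inheritParams apply_suppression
#' @return A suppressed `ring_trajectory`.
#' @export
suppress_trajectory <- function(traj, p) {
  apply_suppression(traj, mean_adapter_rate(traj, p$window), p)
}
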