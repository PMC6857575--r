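#' Model-predicted tilt-aftereffect time course
#'
#' Runs the paired adapter simulations that define the model's TAE: an
#' adapter at `test_orientation + adapter_offset` followed immediately
#' by the test stimulus, and the mirror condition with the adapter at
#' `test_orientation - adapter_offset`.  Each condition is optionally
#' passed through rate suppression (adaptation window = the adapter
#' epoch, offset time `t0` = test onset), decoded with the labeled-line
#' readout, and the TAE is the difference of the two decoded
#' orientations (clockwise-adapter minus counterclockwise-adapter
#' condition, expressed relative to the test orientation).  Positive
#' values are attractive — the percept is pulled toward the adapter.
#'
#' @param params A [network_params()] object.
#' @param adapter_offset Adapter orientation relative to the test,
#'   degrees (nonzero).
#' @param adapter_duration Adapter epoch length, ms.
#' @param test_orientation Test orientation, degrees.
#' @param window Post-onset simulation window, ms.  The default 500 ms
#'   leaves room to measure decay times beyond 300 ms.
#' @param variant Suppression preset name (`"none"`, `"weak"`,
#'   `"strong"`) or a [suppression_params()] object with `t0` at the
#'   test onset.
#' @param contrast Stimulus contrast for both epochs.
#' @param solver A [solver_settings()] object.
#' @return A tibble of class `tae_prediction` with columns `time_ms`
#'   (time since test onset), `tae_deg`, `decoded_cw_deg`,
#'   `decoded_ccw_deg` (decodes relative to the test orientation, in
#'   `[-90, 90)`), and attributes recording the conditions.
#' @examples
#' \donttest{
#' pred <- predict_tae(network_params(n_units = 64), window = 100)
#' tae_at(pred, 50)
#' }
#' @export
predict_tae <- function(params = network_params(), adapter_offset = 20,
                        adapter_duration = 200, test_orientation = 0,
                        window = 500, variant = "none", contrast = 1,
                        solver = solver_settings()) {
  if (adapter_offset == 0) {
    warn("`adapter_offset` is 0: the two conditions coincide and the TAE is identically zero.")
  }
  if (window <= 0) stop_domain("`window` must be positive.")
  t0 <- adapter_duration
  p_sup <- if (inherits(variant, "suppression_params")) variant
           else suppression_preset(variant, t0 = t0)

  one_side <- function(sign) {
    protocol <- stimulus_protocol(
      orientation_deg = c(test_orientation + sign * adapter_offset,
                          test_orientation),
      contrast = contrast,
      duration_ms = c(adapter_duration, window)
    )
    traj <- simulate_ring(protocol, params, solver, keep_voltages = FALSE)
    traj <- suppress_trajectory(traj, p_sup)
    trace <- decode_timecourse(traj)
    dplyr::filter(trace, .data$time_ms >= t0)
  }

  cw <- one_side(+1)
  ccw <- one_side(-1)
  rel_cw <- wrap_orientation(cw$decoded_deg - test_orientation)
  rel_ccw <- wrap_orientation(ccw$decoded_deg - test_orientation)
  out <- tibble(time_ms = cw$time_ms - t0,
                tae_deg = rel_cw - rel_ccw,
                decoded_cw_deg = rel_cw,
                decoded_ccw_deg = rel_ccw)
  class(out) <- c("tae_prediction", class(out))
  attr(out, "variant") <- p_sup$variant %||% "custom"
  attr(out, "suppression") <- p_sup
  attr(out, "adapter_offset") <- adapter_offset
  attr(out, "adapter_duration") <- adapter_duration
  attr(out, "params") <- params
  out
}

#' Evaluate a TAE prediction at given post-onset times
#'
#' `"instantaneous"` interpolates the decoded TAE at the requested
#' times; `"averaged"` returns the running time-average of the TAE
#' from test onset to each requested time, for readouts that integrate
#' over the whole test presentation.
#'
#' @param pred A `tae_prediction`.
#' @param times Times since test onset, ms.
#' @param mode `"instantaneous"` (default) or `"averaged"`.
#' @return TAE values in degrees.
#' @export
tae_at <- function(pred, times, mode = c("instantaneous", "averaged")) {
  mode <- match.arg(mode)
  if (mode == "instantaneous") {
    approx(pred$time_ms, pred$tae_deg, xout = times, rule = 2)$y
  } else {
    t <- pred$time_ms
    cum <- c(0, cumsum(diff(t) * (pred$tae_deg[-1] + pred$tae_deg[-length(t)]) / 2))
    vapply(times, function(tt) {
      approx(t, cum, xout = tt, rule = 2)$y / max(tt - t[1], .Machine$double.eps)
    }, numeric(1))
  }
}

#' Time for the TAE to decay below a threshold
#'
#' First post-onset time at which `|tae|` falls below `threshold` and
#' stays below it for the remainder of the simulated window.
#'
#' @param pred A `tae_prediction`.
#' @param threshold Positive threshold, degrees.
#' @return Time since test onset, ms; `0` if the TAE never reaches the
#'   threshold, `Inf` if it has not decayed below it by the end of the
#'   window.
#' @export
tae_decay_time <- function(pred, threshold = 1) {
  if (threshold <= 0) stop_domain("`threshold` must be positive.")
  above <- abs(pred$tae_deg) >= threshold
  if (!any(above, na.rm = TRUE)) return(0)
  last <- max(which(above))
  if (last == nrow(pred)) return(Inf)
  pred$time_ms[last + 1]
}
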