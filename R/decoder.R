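#' Labeled-line readout of a population rate vector
#'
#' Decodes a perceived orientation from the firing rates of units with
#' fixed preferred orientations.  The default is the population-vector
#' (rate-weighted circular mean) readout on the doubled-angle circle:
#' each preferred orientation `theta` is mapped to `exp(2i * theta)`,
#' the unit vectors are summed with the rates as weights, and the
#' argument of the resultant is halved back to orientation space.  This
#' respects the 180-degree periodicity of orientation and is invariant
#' to uniform rate scaling; the arithmetic rate-weighted mean of the
#' raw angle values is available as `mode = "arithmetic"` for
#' sensitivity checks (it is frame-dependent near the wrap point).
#'
#' @param rates Non-negative firing rates, Hz, one per unit.
#' @param preferred Preferred orientations, degrees, same length.
#' @param mode `"circular"` (default) or `"arithmetic"`.
#' @param min_resultant Minimum mean resultant length below which the
#'   circular decode is declared degenerate (near-uniform activity).
#' @return Decoded orientation in degrees, `[0, 180)`.
#' @examples
#' decode_orientation(c(0, 5, 0), c(10, 37, 90))
#' @export
decode_orientation <- function(rates, preferred,
                               mode = c("circular", "arithmetic"),
                               min_resultant = 1e-6) {
  mode <- match.arg(mode)
  if (length(rates) != length(preferred)) {
    stop_domain("`rates` and `preferred` must have the same length.")
  }
  if (any(rates < 0)) stop_domain("Firing rates must be non-negative.")
  total <- sum(rates)
  if (total <= 0) {
    abort("All rates are zero: decoded orientation is undefined.",
          class = c("ringtae_undefined_decode", "ringtae_decode_error"))
  }
  if (mode == "arithmetic") {
    return(sum(rates * preferred) / total)
  }
  z <- sum(rates * exp(2i * preferred * pi / 180))
  if (Mod(z) / total < min_resultant) {
    abort("Population activity is too uniform on the orientation circle to decode (resultant length below threshold).",
          class = c("ringtae_degenerate_decode", "ringtae_decode_error"))
  }
  (Arg(z) * 90 / pi) %% 180
}

#' Decode a full rate trajectory
#'
#' Applies [decode_orientation()] to every time sample of a simulated
#' trajectory.  Samples with zero total rate are flagged `"undefined"`,
#' samples with near-uniform activity `"degenerate"`; neither is
#' interpolated — the decoded value is `NA` there.
#'
#' @param traj A `ring_trajectory` from [simulate_ring()].
#' @param mode,min_resultant As in [decode_orientation()].
#' @return A tibble of class `decoded_trace` with columns `time_ms`,
#'   `decoded_deg` (degrees in `[0, 180)`), `resultant` (mean resultant
#'   length of the doubled-angle population vector, in `[0, 1]`), and
#'   `flag` (`"ok"`, `"undefined"` or `"degenerate"`).
#' @export
decode_timecourse <- function(traj, mode = c("circular", "arithmetic"),
                              min_resultant = 1e-6) {
  mode <- match.arg(mode)
  rates <- traj$rates
  total <- rowSums(rates)
  z <- as.vector(rates %*% exp(2i * traj$preferred * pi / 180))
  resultant <- ifelse(total > 0, Mod(z) / total, NA_real_)
  flag <- dplyr::case_when(total <= 0 ~ "undefined",
                           resultant < min_resultant ~ "degenerate",
                           TRUE ~ "ok")
  decoded <- if (mode == "circular") {
    (Arg(z) * 90 / pi) %% 180
  } else {
    as.vector(rates %*% traj$preferred) / total
  }
  decoded[flag != "ok"] <- NA_real_
  out <- tibble(time_ms = traj$times, decoded_deg = decoded,
                resultant = resultant, flag = flag)
  class(out) <- c("decoded_trace", class(out))
  out
}
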