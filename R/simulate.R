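#' Simulate the recurrent orientation ring
#'
#' Integrates the membrane-potential dynamics of `n_units` recurrently
#' connected orientation-tuned units,
#' `tau * dV/dt = -V + V_lgn + V_cortex`,
#' where the feedforward drive `V_lgn` is a contrast-scaled von Mises
#' function of the stimulus orientation ([lgn_drive()]) and the
#' recurrent input is the Mexican-hat-weighted population rate,
#' `V_cortex(theta) = sum_phi F_theta(phi) R_phi dphi` with
#' `dphi = pi / n_units` ([connection_profile()]).  Firing rates are the
#' rectified linear readout `R = alpha * max(V, 0)`.
#'
#' Each epoch is integrated separately with the previous epoch's final
#' state as initial state, so the adaptive solver never steps across
#' the instantaneous drive switch at an epoch boundary.  The simulation
#' starts from rest (`V = 0`) — each simulated trial begins with no
#' carry-over.
#'
#' @param protocol A [stimulus_protocol()].
#' @param params A [network_params()] object.
#' @param solver A [solver_settings()] object.
#' @param keep_voltages Retain the membrane-potential matrix alongside
#'   the rates?
#' @return A `ring_trajectory`: list with `times` (ms, regular grid from
#'   0 spanning the protocol), `preferred` (degrees), `rates` (time x
#'   unit matrix, Hz), optionally `voltages` (mV), and the inputs.
#' @examples
#' traj <- simulate_ring(
#'   stimulus_protocol(c(20, 0), 1, c(200, 100)),
#'   network_params(n_units = 64)
#' )
#' dim(traj$rates)
#' @export
simulate_ring <- function(protocol, params = network_params(),
                          solver = solver_settings(),
                          keep_voltages = TRUE) {
  if (!inherits(protocol, "stimulus_protocol")) {
    protocol <- stimulus_protocol(protocol$orientation_deg,
                                  protocol$contrast %||% 1,
                                  protocol$duration_ms)
  }
  if (params$n_units != 256L && is_default_constants(params)) {
    warn(paste0("The default network constants were calibrated with 256 units; ",
                "n_units = ", params$n_units, " uses them outside that calibration."),
         class = "ringtae_n_units_warning")
  }

  n <- params$n_units
  theta <- preferred_orientations(n)
  W <- connection_matrix(params)
  total <- protocol_duration(protocol)
  dt <- solver$dt_out
  grid <- seq(0, total, by = dt)
  if (grid[length(grid)] < total - 1e-9) grid <- c(grid, total)

  V <- matrix(NA_real_, nrow = length(grid), ncol = n)
  V[1, ] <- 0
  state <- rep(0, n)
  bounds <- c(0, cumsum(protocol$duration_ms))
  eps <- dt * 1e-8

  deriv <- function(t, v, parms) {
    r <- params$alpha * pmax(v, 0)
    list((-v + parms$vlgn + as.vector(W %*% r)) / params$tau)
  }

  for (e in seq_len(nrow(protocol))) {
    t0 <- bounds[e]; t1 <- bounds[e + 1]
    sel <- which(grid > t0 + eps & grid <= t1 + eps)
    local_times <- sort(unique(c(0, grid[sel] - t0, t1 - t0)))
    # collapse floating-point near-duplicates (ascending times required)
    local_times <- local_times[c(TRUE, diff(local_times) > eps)]
    vlgn <- lgn_drive(theta, protocol$orientation_deg[e],
                      protocol$contrast[e], params)
    out <- tryCatch(
      deSolve::ode(y = state, times = local_times, func = deriv,
                   parms = list(vlgn = vlgn),
                   method = deSolve::rkMethod("ode45"),
                   rtol = solver$rtol, atol = solver$atol),
      error = function(cnd) {
        abort(paste0("Integration failed in epoch ", e, " (t in [",
                     t0, ", ", t1, "] ms): ", conditionMessage(cnd)),
              class = "ringtae_integration_error")
      }
    )
    sol <- out[, -1, drop = FALSE]
    if (any(!is.finite(sol))) {
      bad <- local_times[which(rowSums(!is.finite(sol)) > 0)[1]] + t0
      abort(paste0("Non-finite network state at t = ", bad, " ms."),
            class = "ringtae_integration_error")
    }
    if (length(sel)) {
      idx <- vapply(grid[sel] - t0,
                    function(v) which.min(abs(local_times - v)), integer(1))
      V[sel, ] <- sol[idx, , drop = FALSE]
    }
    state <- sol[nrow(sol), ]
  }

  traj <- list(times = grid, preferred = theta,
               rates = params$alpha * pmax(V, 0),
               voltages = if (keep_voltages) V else NULL,
               params = params, protocol = protocol, solver = solver)
  class(traj) <- "ring_trajectory"
  traj
}

#' @export
print.ring_trajectory <- function(x, ...) {
  cat("<ring_trajectory>", length(x$times), "samples x",
      length(x$preferred), "units,",
      sprintf("t = [%g, %g] ms\n", min(x$times), max(x$times)))
  cat(sprintf("  peak rate %.3g Hz; voltages %s\n", max(x$rates),
              if (is.null(x$voltages)) "dropped" else "retained"))
  invisible(x)
}

#' Long-format view of a rate trajectory
#'
#' @param x A `ring_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time_ms`, `preferred_deg`, `rate_hz`.
#' @method tidy ring_trajectory
#' @export
tidy.ring_trajectory <- function(x, ...) {
  tibble(time_ms = rep(x$times, times = length(x$preferred)),
         preferred_deg = rep(x$preferred, each = length(x$times)),
         rate_hz = as.vector(x$rates))
}

#' @method as_tibble ring_trajectory
#' @export
as_tibble.ring_trajectory <- function(x, ...) tidy(x)

#' Write a rate trajectory as a delimited long-format table
#'
#' @param traj A `ring_trajectory`.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(tidy(traj), path)
  invisible(path)
}
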