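# Independent oracles, written without reference to the package internals.

# Modified Bessel function of order zero by its power series.
i0_series <- function(x, terms = 40) {
  k <- 0:(terms - 1)
  sum((x / 2)^(2 * k) / factorial(k)^2)
}

# Reference 180-degree-periodic von Mises density via the series Bessel.
vm_ref <- function(x_deg, mu_deg, kappa) {
  exp(kappa * cos(2 * (x_deg - mu_deg) * pi / 180)) / (2 * pi * i0_series(kappa))
}

# Fixed-step forward-Euler integration of the ring network, dt in ms.
# Independent re-derivation: builds its own drive and weight matrix from
# the model constants and steps the ODE explicitly.
euler_ring <- function(protocol, par, dt = 0.01, out_dt = 1) {
  n <- par$n_units
  th <- (0:(n - 1)) * 180 / n
  W <- (pi / n) * par$j_cortex *
    (vm_ref(outer(th, th, "-"), 0, par$kappa_e) -
       par$r_ie * vm_ref(outer(th, th, "-"), 0, par$kappa_i))
  total <- sum(protocol$duration_ms)
  out_times <- seq(0, total, by = out_dt)
  V <- rep(0, n)
  out <- matrix(NA_real_, length(out_times), n)
  out[1, ] <- 0
  bounds <- cumsum(protocol$duration_ms)
  t <- 0
  next_out <- 2
  n_steps <- round(total / dt)
  for (s in seq_len(n_steps)) {
    e <- findInterval(t, bounds, left.open = FALSE) + 1  # epoch of [t, t+dt)
    vlgn <- protocol$contrast[e] * par$j_lgn *
      vm_ref(th, protocol$orientation_deg[e], par$kappa_lgn)
    R <- par$alpha * pmax(V, 0)
    V <- V + dt * (-V + vlgn + as.vector(W %*% R)) / par$tau
    t <- s * dt
    while (next_out <= length(out_times) && t >= out_times[next_out] - 1e-9) {
      out[next_out, ] <- V
      next_out <- next_out + 1
    }
  }
  list(times = out_times, voltages = out, rates = par$alpha * pmax(out, 0),
       preferred = th)
}

# Bernoulli trial generator from a lapse-padded logistic observer.
gen_logistic_trials <- function(n_per_offset, pse, slope, lapse,
                                offsets = seq(-12, 12, by = 4)) {
  x <- rep(offsets, each = n_per_offset)
  p <- lapse + (1 - 2 * lapse) * plogis(slope * (x - pse))
  data.frame(test_offset_deg = x, response_cw = runif(length(x)) < p)
}

# Simulate with a reduced unit count, muting the 256-unit calibration
# warning that is expected (and separately tested) for such calls.
quiet_sim <- function(protocol, params, ...) {
  suppressWarnings(simulate_ring(protocol, params, ...))
}
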