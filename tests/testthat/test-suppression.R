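make_traj <- function(times, rates, preferred = (0:(ncol(rates) - 1)) * 180 / ncol(rates)) {
  structure(list(times = times, preferred = preferred, rates = rates,
                 voltages = NULL), class = "ring_trajectory")
}

test_that("mean adapter rate is the time average over [start, end)", {
  tm <- 0:100
  n <- 8
  # constant rates average to themselves
  const <- make_traj(tm, matrix(rep(3, length(tm) * n), ncol = n))
  expect_equal(mean_adapter_rate(const, c(0, 50)), rep(3, n))
  # zero trajectory averages to zero
  zero <- make_traj(tm, matrix(0, length(tm), n))
  expect_equal(mean_adapter_rate(zero, c(10, 60)), rep(0, n))
  # linear ramp 0 -> 10 Hz: close to 5 Hz, exactly the grid-sample mean
  ramp <- make_traj(tm, matrix(rep(tm / 10, n), ncol = n))
  got <- mean_adapter_rate(ramp, c(0, 100))
  expect_equal(got, rep(mean((0:99) / 10), n))
  expect_equal(got, rep(5, n), tolerance = 0.02)
  expect_error(mean_adapter_rate(ramp, c(50, 50)), class = "ringtae_domain_error")
  expect_error(mean_adapter_rate(ramp, c(200, 300)), class = "ringtae_domain_error")
})

test_that("suppression follows the exponential-recovery law and clips at zero", {
  tm <- 0:300
  n <- 4
  rates <- matrix(rep(c(10, 6, 2, 0.5), each = length(tm)), ncol = n)
  traj <- make_traj(tm, rates)
  mr <- mean_adapter_rate(traj, c(0, 100))
  p <- suppression_params(beta = 0.5, rho = 50, t0 = 100)
  out <- apply_suppression(traj, mr, p)

  # untouched before t0
  expect_equal(out$rates[tm < 100, ], rates[tm < 100, ])
  # at t0 exactly: R - beta * <R> (no clipping for these values)
  expect_equal(out$rates[tm == 100, ], rates[tm == 100, ] - 0.5 * mr,
               ignore_attr = TRUE)
  # exponential recovery mid-course
  expect_equal(out$rates[tm == 150, ],
               rates[tm == 150, ] - 0.5 * mr * exp(-1),
               ignore_attr = TRUE)
  # far beyond rho the correction is negligible
  expect_lt(max(abs(out$rates[length(tm), ] - rates[length(tm), ])),
            0.5 * max(mr) * exp(-(300 - 100) / 50) + 1e-12)
  # rates never negative, never exceed the input after t0
  expect_true(all(out$rates >= 0))
  expect_true(all(out$rates[tm >= 100, ] <= rates[tm >= 100, ] + 1e-12))
  # beta = 0 is the identity
  none <- apply_suppression(traj, mr, suppression_params(0, 100, t0 = 100))
  expect_equal(none$rates, rates)
})

test_that("clipping engages when the correction crosses zero", {
  tm <- 0:200
  rates <- matrix(rep(c(1, 8), each = length(tm)), ncol = 2)
  traj <- make_traj(tm, rates)
  p <- suppression_params(beta = 1, rho = 500, t0 = 100)
  out <- suppress_trajectory(traj, p)
  # unit 1: 1 - 1*1*exp(~0) < 0 -> clipped to 0 at t0
  expect_equal(out$rates[tm == 100, 1], 0)
  expect_true(all(out$rates >= 0))
})

test_that("suppression magnitude is monotone in beta and in the mean rate", {
  tm <- 0:150
  rates <- matrix(rep(c(10, 4, 7), each = length(tm)), ncol = 3)
  traj <- make_traj(tm, rates)
  mr <- mean_adapter_rate(traj, c(0, 100))
  at <- function(beta, scale = 1) {
    apply_suppression(traj, scale * mr,
                      suppression_params(beta, 80, t0 = 100))$rates[tm == 120, ]
  }
  expect_true(all(at(0.2) >= at(0.5)))
  expect_true(all(at(0.5) >= at(0.8)))
  expect_true(all(at(0.5, scale = 0.5) >= at(0.5, scale = 1)))
})

test_that("untuned (uniform) suppression leaves the decode unchanged when unclipped", {
  th <- (0:31) * 180 / 32
  tm <- 0:120
  rates <- outer(rep(1, length(tm)), 5 + 40 * von_mises_density(th, 20, 2))
  traj <- make_traj(tm, rates, th)
  p <- suppression_params(beta = 0.3, rho = 100, t0 = 100)
  out <- apply_suppression(traj, rep(2, 32), p)  # uniform <R>
  expect_true(all(out$rates > 0))  # no clipping occurred
  d0 <- decode_orientation(traj$rates[120, ], th)
  d1 <- decode_orientation(out$rates[120, ], th)
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("suppression presets encode the two estimated regimes", {
  w <- suppression_preset("weak", t0 = 200)
  s <- suppression_preset("strong", t0 = 200)
  n <- suppression_preset("none", t0 = 200)
  expect_equal(c(w$beta, w$rho), c(0.20, 100))
  expect_equal(c(s$beta, s$rho), c(0.50, 500))
  expect_equal(n$beta, 0)
  expect_error(suppression_params(1.2, 100, 100), class = "ringtae_domain_error")
  expect_error(suppression_params(0.5, -1, 100), class = "ringtae_domain_error")
  expect_error(suppression_params(0.5, 100, t0 = 100, window = c(0, 90)),
               class = "ringtae_domain_error")
})
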