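test_that("generate-and-refit recovers known psychometric parameters", {
  withr::local_seed(41)
  trials <- gen_logistic_trials(300, pse = 2, slope = 0.5, lapse = 0.02)
  fit <- fit_logistic(trials, n_boot = 300)
  ci <- confint(fit)
  expect_true(ci[1] <= 2 && 2 <= ci[2])
  expect_equal(fit$pse, 2, tolerance = 0.5)
  expect_equal(fit$slope, 0.5, tolerance = 0.35)

  # refitting with the generating lapse fixed: PSE still near truth
  trials0 <- gen_logistic_trials(300, pse = 0, slope = 0.5, lapse = 0.05)
  fit0 <- fit_logistic(trials0, fixed_lapse = 0.05, n_boot = 300)
  ci0 <- confint(fit0)
  expect_true(ci0[1] <= 0 && 0 <= ci0[2])
  expect_true(fit0$lapse_fixed)
  expect_equal(fit0$lapse, 0.05)
})

test_that("the fit is deterministic and degenerate data are rejected", {
  withr::local_seed(7)
  trials <- gen_logistic_trials(80, pse = -1, slope = 0.4, lapse = 0)
  f1 <- fit_logistic(trials)
  f2 <- fit_logistic(trials)
  expect_identical(f1$pse, f2$pse)
  expect_identical(f1$slope, f2$slope)

  # exactly 50/50 responses at every offset: slope ~ 0, PSE unidentifiable
  flat <- data.frame(test_offset_deg = rep(seq(-12, 12, 4), each = 40),
                     response_cw = rep(c(TRUE, FALSE), times = 7 * 20))
  expect_error(fit_logistic(flat, fixed_lapse = 0),
               class = "ringtae_degenerate_fit")
  # a single offset is insufficient
  expect_error(fit_logistic(data.frame(test_offset_deg = rep(0, 10),
                                       response_cw = rep(TRUE, 10))),
               class = "ringtae_domain_error")
  expect_error(fit_logistic(trials, fixed_lapse = 0.5),
               class = "ringtae_domain_error")
})

test_that("pooled lapse estimation recovers the generating lapse", {
  withr::local_seed(11)
  cw <- gen_logistic_trials(300, pse = 1.5, slope = 0.5, lapse = 0.05)
  ccw <- gen_logistic_trials(300, pse = -1.5, slope = 0.5, lapse = 0.05)
  lam <- estimate_lapse_pooled(cw, ccw)
  expect_gte(lam, 0.02)
  expect_lte(lam, 0.08)

  # lapse-free generator: estimate collapses to (near) the boundary
  cw0 <- gen_logistic_trials(400, pse = 0, slope = 0.5, lapse = 0)
  ccw0 <- gen_logistic_trials(400, pse = 0, slope = 0.5, lapse = 0)
  expect_lte(estimate_lapse_pooled(cw0, ccw0), 0.02)

  # pooling two identical sets equals fitting one alone
  expect_equal(estimate_lapse_pooled(cw, cw), fit_logistic(cw)$lapse,
               tolerance = 1e-5)
  expect_error(estimate_lapse_pooled(cw[0, ], ccw),
               class = "ringtae_domain_error")
})

test_that("PSE difference is signed, antisymmetric, and doubles a per-condition shift", {
  withr::local_seed(23)
  lam <- 0.02
  cw <- gen_logistic_trials(400, pse = 3, slope = 0.5, lapse = lam)
  ccw <- gen_logistic_trials(400, pse = -3, slope = 0.5, lapse = lam)
  f1 <- fit_logistic(cw, fixed_lapse = lam, n_boot = 300)
  f2 <- fit_logistic(ccw, fixed_lapse = lam, n_boot = 300)
  expect_equal(pse_difference(f1, f1), 0)
  expect_equal(pse_difference(f1, f2), -pse_difference(f2, f1))
  d <- pse_difference(f1, f2)
  m <- min(length(f1$boot_pse), length(f2$boot_pse))
  ci <- quantile(f1$boot_pse[1:m] - f2$boot_pse[1:m], c(0.025, 0.975))
  expect_true(ci[1] <= 6 && 6 <= ci[2])
  expect_equal(d, 6, tolerance = 1)
})

test_that("Monte Carlo PSE comparison is seed-deterministic and detects a large shift", {
  withr::local_seed(31)
  cw <- gen_logistic_trials(300, pse = 5, slope = 0.5, lapse = 0.02)
  ccw <- gen_logistic_trials(300, pse = -5, slope = 0.5, lapse = 0.02)
  m1 <- monte_carlo_pse_test(cw, ccw, n_resamples = 500, seed = 99)
  m2 <- monte_carlo_pse_test(cw, ccw, n_resamples = 500, seed = 99)
  expect_identical(m1$p_value, m2$p_value)
  expect_lt(m1$p_value, 0.01)
  expect_equal(m1$tae, 10, tolerance = 1.5)
  expect_error(monte_carlo_pse_test(cw, ccw, n_resamples = 100),
               class = "ringtae_domain_error")
  # the seeded run must not consume the caller's RNG stream
  before <- .Random.seed
  invisible(monte_carlo_pse_test(cw, ccw, n_resamples = 500, seed = 1))
  expect_identical(before, .Random.seed)
})

test_that("catch-trial visibility statistic behaves at its extremes and under chance", {
  # all responses consistent with the adapter-reference relation
  all_cons <- data.frame(ref_offset_deg = rep(c(-20, 20), each = 10),
                         response_cw = rep(c(TRUE, FALSE), each = 10))
  v <- catch_visibility(all_cons)
  expect_equal(v$visibility, 0.5)
  expect_lt(v$p_value, 1e-4)
  # a single consistent trial: maximal visibility but no evidence
  one <- catch_visibility(data.frame(ref_offset_deg = -20, response_cw = TRUE))
  expect_equal(one$visibility, 0.5)
  expect_equal(one$p_value, 1)
  # coin-flip responses: small visibility, non-significant
  withr::local_seed(5)
  coin <- data.frame(ref_offset_deg = sample(c(-20, 20), 200, TRUE),
                     response_cw = runif(200) < 0.5)
  vc <- catch_visibility(coin)
  expect_lt(abs(vc$visibility), 0.12)
  expect_gt(vc$p_value, 0.05)
  expect_error(catch_visibility(coin[0, ]), class = "ringtae_domain_error")
})

test_that("tidy, glance, predict and plotting surfaces are consistent", {
  withr::local_seed(3)
  trials <- gen_logistic_trials(120, pse = 1, slope = 0.5, lapse = 0.02)
  fit <- fit_logistic(trials, fixed_lapse = 0.02)
  td <- tidy(fit)
  expect_equal(td$term, c("pse", "slope", "lapse"))
  expect_equal(td$estimate[1], fit$pse)
  gl <- glance(fit)
  expect_equal(gl$n_trials, nrow(trials))
  # predictions live inside the lapse-padded band and hit 0.5 at the PSE
  p <- predict(fit, seq(-30, 30, 1))
  expect_true(all(p >= fit$lapse & p <= 1 - fit$lapse))
  expect_equal(predict(fit, fit$pse), 0.5)
  expect_s3_class(autoplot(fit), "ggplot")
})
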