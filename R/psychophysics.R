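#' Fit a logistic psychometric function
#'
#' Maximum-likelihood fit of the lapse-padded logistic
#' `P(CW) = lambda + (1 - 2 * lambda) / (1 + exp(-slope * (x - pse)))`
#' to binary clockwise/counterclockwise responses, where `x` is the
#' signed test-minus-reference orientation offset.  A single symmetric
#' lapse rate `lambda` pads both asymptotes.  When `fixed_lapse` is
#' given, only `(pse, slope)` are fitted — the second stage of the
#' two-stage procedure in which `lambda` is first estimated from
#' pooled data ([estimate_lapse_pooled()]) and then held fixed per
#' condition.
#'
#' The optimizer is started from a probit fit on the aggregated
#' proportions (slope) and the 50% crossing of a linear interpolation
#' (PSE), with two additional perturbed starts; the best likelihood is
#' kept, making the fit deterministic for a given data set.
#'
#' @param trials Data frame with columns `test_offset_deg` and
#'   `response_cw` (logical or 0/1).  Rows with `is_catch == TRUE` are
#'   dropped if that column is present.
#' @param fixed_lapse Optional lapse rate in `[0, 0.2]` to hold fixed.
#' @param lapse_max Upper bound for a freely estimated lapse rate
#'   (default 0.1, preventing the slope-lapse trade-off).
#' @param n_boot Number of parametric-bootstrap resamples of the PSE to
#'   attach (0 = none); used by [confint.psychometric_fit()].
#' @param condition Optional label stored with the fit.
#' @return An object of class `psychometric_fit` with elements `pse`
#'   (degrees), `slope` (per degree), `lapse`, `lapse_fixed`,
#'   `n_trials`, `logLik`, `data` (aggregated counts) and optional
#'   `boot_pse`.
#' @examples
#' x <- rep(seq(-12, 12, 4), each = 50)
#' set.seed(1)
#' y <- runif(length(x)) < plogis(0.5 * (x - 2))
#' fit <- fit_logistic(data.frame(test_offset_deg = x, response_cw = y))
#' fit$pse
#' @export
fit_logistic <- function(trials, fixed_lapse = NULL, lapse_max = 0.1,
                         n_boot = 0, condition = NULL) {
  agg <- aggregate_trials(trials)
  if (nrow(agg) < 2) {
    stop_domain("Need responses at two or more distinct test offsets.")
  }
  if (!is.null(fixed_lapse) && (fixed_lapse < 0 || fixed_lapse > 0.2)) {
    stop_domain("`fixed_lapse` must lie in [0, 0.2].")
  }
  fit <- ml_logistic(agg$x, agg$n, agg$k, fixed_lapse, lapse_max)
  if (fit$degenerate) {
    abort(paste0("Degenerate psychometric fit: ", fit$reason,
                 " (slope = ", signif(fit$slope, 3), "/deg)."),
          class = "ringtae_degenerate_fit")
  }
  boot_pse <- NULL
  if (n_boot > 0) {
    p_hat <- psychometric_prob(agg$x, fit$pse, fit$slope, fit$lapse)
    boot_pse <- vapply(seq_len(n_boot), function(b) {
      kb <- rbinom(length(agg$n), agg$n, p_hat)
      rf <- ml_logistic(agg$x, agg$n, kb, fit$lapse, lapse_max,
                        start = c(fit$pse, fit$slope))
      if (rf$degenerate) NA_real_ else rf$pse
    }, numeric(1))
    boot_pse <- boot_pse[!is.na(boot_pse)]
  }
  structure(list(pse = fit$pse, slope = fit$slope, lapse = fit$lapse,
                 lapse_fixed = !is.null(fixed_lapse),
                 n_trials = sum(agg$n), logLik = fit$logLik,
                 data = agg, boot_pse = boot_pse,
                 condition = condition),
            class = "psychometric_fit")
}

# Collapse trials to per-offset binomial counts.
aggregate_trials <- function(trials) {
  if ("is_catch" %in% names(trials)) {
    trials <- trials[!trials$is_catch, , drop = FALSE]
  }
  if (!all(c("test_offset_deg", "response_cw") %in% names(trials))) {
    stop_domain("`trials` needs columns `test_offset_deg` and `response_cw`.")
  }
  x <- trials$test_offset_deg
  y <- as.logical(trials$response_cw)
  if (any(!is.finite(x)) || any(is.na(y))) {
    stop_domain("Non-finite test offsets or missing responses in `trials`.")
  }
  out <- dplyr::summarise(dplyr::group_by(tibble(x = x, y = y), .data$x),
                          n = dplyr::n(), k = sum(.data$y), .groups = "drop")
  dplyr::arrange(out, .data$x)
}

psychometric_prob <- function(x, pse, slope, lapse) {
  lapse + (1 - 2 * lapse) * plogis(slope * (x - pse))
}

# Negative log-likelihood and analytic gradient on aggregated counts.
nll_counts <- function(par, x, n, k, lapse) {
  p <- pmin(pmax(psychometric_prob(x, par[1], par[2], lapse), 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

grad_counts <- function(par, x, n, k, lapse) {
  s <- plogis(par[2] * (x - par[1]))
  p <- pmin(pmax(lapse + (1 - 2 * lapse) * s, 1e-12), 1 - 1e-12)
  dldp <- -(k / p - (n - k) / (1 - p))
  core <- (1 - 2 * lapse) * s * (1 - s)
  c(sum(dldp * core * (-par[2])), sum(dldp * core * (x - par[1])))
}

# Core ML engine on aggregated counts; returns a plain list and never
# throws for degeneracy (callers decide).
ml_logistic <- function(x, n, k, fixed_lapse = NULL, lapse_max = 0.1,
                        start = NULL) {
  prop <- (k + 0.5) / (n + 1)
  single_start <- !is.null(start)  # bootstrap refits restart from the fit
  if (is.null(start)) {
    slope0 <- tryCatch({
      g <- suppressWarnings(glm(cbind(k, n - k) ~ x,
                                family = binomial("probit")))
      max(abs(coef(g)[2]) * 1.7, 0.01)  # probit -> logistic scale
    }, error = function(e) 0.25)
    pse0 <- crossing_50(x, prop)
    start <- c(pse0, slope0)
  }
  lo <- c(min(x) - 50, 1e-4)
  hi <- c(max(x) + 50, 50)
  start <- pmin(pmax(start, lo), hi)
  span <- diff(range(x))
  starts <- if (single_start) list(start) else
    list(start,
         c(start[1] + 0.2 * span, start[2] * 0.5),
         c(start[1] - 0.2 * span, start[2] * 2))

  run2 <- function(st, lapse) {
    o <- tryCatch(
      optim(pmin(pmax(st, lo), hi), nll_counts, gr = grad_counts,
            x = x, n = n, k = k, lapse = lapse,
            method = "L-BFGS-B", lower = lo, upper = hi),
      error = function(e) NULL)
    o
  }

  if (!is.null(fixed_lapse)) {
    fits <- purrr::compact(lapply(starts, run2, lapse = fixed_lapse))
    if (!length(fits)) {
      return(list(degenerate = TRUE, reason = "optimizer failure",
                  pse = NA_real_, slope = NA_real_))
    }
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    res <- list(pse = best$par[1], slope = best$par[2], lapse = fixed_lapse,
                logLik = -best$value)
  } else {
    run3 <- function(st) {
      tryCatch(
        optim(c(pmin(pmax(st, lo), hi), pmin(0.02, lapse_max)),
              function(par) nll_counts(par[1:2], x, n, k, par[3]),
              method = "L-BFGS-B",
              lower = c(lo, 0), upper = c(hi, lapse_max)),
        error = function(e) NULL)
    }
    fits <- purrr::compact(lapply(starts, run3))
    if (!length(fits)) {
      return(list(degenerate = TRUE, reason = "optimizer failure",
                  pse = NA_real_, slope = NA_real_))
    }
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    res <- list(pse = best$par[1], slope = best$par[2], lapse = best$par[3],
                logLik = -best$value)
  }
  res$degenerate <- FALSE
  if (res$slope <= 5e-3) {
    res$degenerate <- TRUE
    res$reason <- "slope indistinguishable from zero; PSE unidentifiable"
  } else if (res$slope >= 49) {
    res$degenerate <- TRUE
    res$reason <- "perfect separation; slope unbounded"
  }
  res
}

crossing_50 <- function(x, prop) {
  cross <- which(diff(sign(prop - 0.5)) != 0)
  if (length(cross)) {
    i <- cross[1]
    x[i] + (0.5 - prop[i]) * (x[i + 1] - x[i]) /
      (prop[i + 1] - prop[i] + 1e-12)
  } else {
    x[which.min(abs(prop - 0.5))]
  }
}

#' Pooled lapse-rate estimation
#'
#' First stage of the two-stage fitting procedure: a single logistic
#' fit to the clockwise- and counterclockwise-adapter trials pooled
#' together yields the subject's lapse rate, which is then held fixed
#' in the per-condition refits.  The lapse is constrained to
#' `[0, lapse_max]` (default 0.1) to prevent the slope-lapse
#' trade-off.
#'
#' @param trials_cw,trials_ccw Trial tables for the two adapter
#'   conditions (see [fit_logistic()] for required columns).
#' @param lapse_max Upper bound for the lapse rate.
#' @return The estimated lapse rate (scalar).
#' @export
estimate_lapse_pooled <- function(trials_cw, trials_ccw, lapse_max = 0.1) {
  if (!nrow(trials_cw) || !nrow(trials_ccw)) {
    stop_domain("Both trial sets must be non-empty.")
  }
  pooled <- dplyr::bind_rows(trials_cw, trials_ccw)
  fit <- fit_logistic(pooled, fixed_lapse = NULL, lapse_max = lapse_max)
  fit$lapse
}

#' PSE-difference tilt aftereffect
#'
#' The behavioral TAE: the difference of the points of subjective
#' equality of the clockwise-adapter and counterclockwise-adapter
#' psychometric functions, oriented so that a positive value indicates
#' an attractive shift (the perceived test is pulled toward the
#' adapter).  `fit_cw` must be the condition with a positive
#' reference-minus-adapter offset.
#'
#' @param fit_cw,fit_ccw `psychometric_fit` objects for the two
#'   conditions, fitted with the same fixed lapse.
#' @return Signed TAE in degrees.
#' @export
pse_difference <- function(fit_cw, fit_ccw) {
  stopifnot(inherits(fit_cw, "psychometric_fit"),
            inherits(fit_ccw, "psychometric_fit"))
  fit_cw$pse - fit_ccw$pse
}

#' Monte Carlo comparison of two psychometric functions
#'
#' Parametric-bootstrap test of the null hypothesis that the two
#' conditions share a PSE.  Both conditions are fitted (lapse fixed to
#' the pooled estimate), new response sets are simulated from each
#' fitted curve at the observed stimulus placements, both are refitted,
#' and the resampled PSE differences — re-centred at zero — form the
#' null distribution against which the observed difference is compared
#' two-sidedly.
#'
#' @inheritParams estimate_lapse_pooled
#' @param n_resamples Number of bootstrap resamples (at least 500).
#' @param seed Optional integer seed; the test is reproducible given
#'   the seed and does not disturb the caller's RNG stream.
#' @param lapse Optional lapse rate; when `NULL` it is estimated with
#'   [estimate_lapse_pooled()].
#' @return A list of class `pse_mc_test` with elements `tae` (observed
#'   PSE difference, degrees), `p_value` (two-sided), `null_sd`,
#'   `n_resamples`, `n_failed` and `lapse`.  Errors out if more than 5%
#'   of resampled refits fail.
#' @export
monte_carlo_pse_test <- function(trials_cw, trials_ccw, n_resamples = 2000,
                                 seed = NULL, lapse = NULL) {
  if (n_resamples < 500) stop_domain("`n_resamples` must be at least 500.")
  if (is.null(lapse)) lapse <- estimate_lapse_pooled(trials_cw, trials_ccw)
  fit1 <- fit_logistic(trials_cw, fixed_lapse = lapse)
  fit2 <- fit_logistic(trials_ccw, fixed_lapse = lapse)
  observed <- pse_difference(fit1, fit2)

  draw <- function() {
    d1 <- refit_resample(fit1, lapse)
    d2 <- refit_resample(fit2, lapse)
    if (is.na(d1) || is.na(d2)) NA_real_ else d1 - d2
  }
  diffs <- if (is.null(seed)) {
    vapply(seq_len(n_resamples), function(b) draw(), numeric(1))
  } else {
    withr::with_seed(seed,
      vapply(seq_len(n_resamples), function(b) draw(), numeric(1)))
  }
  failed <- sum(is.na(diffs))
  if (failed > 0.05 * n_resamples) {
    abort(paste0(failed, " of ", n_resamples,
                 " bootstrap refits failed (> 5%); the comparison is unreliable."),
          class = "ringtae_degenerate_fit")
  }
  diffs <- diffs[!is.na(diffs)]
  null <- diffs - mean(diffs)
  p <- (1 + sum(abs(null) >= abs(observed))) / (length(null) + 1)
  structure(list(tae = observed, p_value = p, null_sd = sd(null),
                 n_resamples = n_resamples, n_failed = failed,
                 lapse = lapse),
            class = "pse_mc_test")
}

refit_resample <- function(fit, lapse) {
  agg <- fit$data
  p_hat <- psychometric_prob(agg$x, fit$pse, fit$slope, lapse)
  kb <- rbinom(nrow(agg), agg$n, p_hat)
  rf <- ml_logistic(agg$x, agg$n, kb, lapse, start = c(fit$pse, fit$slope))
  if (rf$degenerate) NA_real_ else rf$pse
}

#' @export
print.pse_mc_test <- function(x, ...) {
  cat("Monte Carlo (parametric bootstrap) PSE comparison\n")
  cat(sprintf("  TAE (PSE difference): %.3f deg\n", x$tae))
  cat(sprintf("  two-sided p = %.4g  (%d resamples, %d failed)\n",
              x$p_value, x$n_resamples, x$n_failed))
  invisible(x)
}

#' Catch-trial visibility of the adapter
#'
#' On catch trials the test stimulus is replaced by an unoriented
#' pattern, leaving the adapter as the only oriented element on the
#' test side.  If the adapter were visible, responses should be
#' consistent with the adapter-vs-reference relation: report "test
#' side more clockwise" exactly when the adapter is clockwise of the
#' reference (i.e. when `ref_offset_deg < 0`, positive angles being
#' clockwise).  Visibility is the proportion of consistent responses
#' minus 50%, with an exact two-sided binomial test against chance.
#'
#' @param catch_trials Trial table containing only catch trials, with
#'   columns `ref_offset_deg` and `response_cw`.
#' @return One-row tibble: `n`, `n_consistent`, `visibility`
#'   (proportion minus 0.5), `p_value`.
#' @export
catch_visibility <- function(catch_trials) {
  if ("is_catch" %in% names(catch_trials)) {
    catch_trials <- catch_trials[as.logical(catch_trials$is_catch), ,
                                 drop = FALSE]
  }
  n <- nrow(catch_trials)
  if (n < 1) stop_domain("Need at least one catch trial.")
  consistent <- as.logical(catch_trials$response_cw) ==
    (catch_trials$ref_offset_deg < 0)
  k <- sum(consistent)
  tibble(n = n, n_consistent = k, visibility = k / n - 0.5,
         p_value = binom.test(k, n, 0.5)$p.value)
}

#' Full behavioral TAE analysis of a trial table
#'
#' Convenience chain reproducing the standard analysis: a pooled lapse
#' estimate per subject, fixed-lapse logistic fits per test duration
#' and adapter side (trials grouped by the *sign* of the
#' reference-minus-adapter offset, ignoring its jitter), the
#' PSE-difference TAE per duration, optionally a Monte Carlo p-value,
#' and the catch-trial visibility.
#'
#' @param trials Trial table with columns `ref_offset_deg`,
#'   `test_offset_deg`, `duration_ms`, `is_catch`, `response_cw`.
#' @param n_resamples Monte Carlo resamples per duration (0 skips the
#'   test).
#' @param seed Seed forwarded to [monte_carlo_pse_test()].
#' @param lapse_max Bound for the pooled lapse estimate.
#' @return A list with `lapse`, `by_duration` (tibble: `duration_ms`,
#'   `pse_cw`, `pse_ccw`, `tae_deg`, `n_trials`, and `p_value` when
#'   resampling), and `catch` (from [catch_visibility()], or `NULL`
#'   with no catch trials).
#' @export
tae_analysis <- function(trials, n_resamples = 0, seed = NULL,
                         lapse_max = 0.1) {
  main <- trials[!as.logical(trials$is_catch), , drop = FALSE]
  cw <- main[main$ref_offset_deg > 0, , drop = FALSE]
  ccw <- main[main$ref_offset_deg < 0, , drop = FALSE]
  lapse <- estimate_lapse_pooled(cw, ccw, lapse_max = lapse_max)
  by_dur <- purrr::map_dfr(sort(unique(main$duration_ms)), function(d) {
    cw_d <- cw[cw$duration_ms == d, , drop = FALSE]
    ccw_d <- ccw[ccw$duration_ms == d, , drop = FALSE]
    f1 <- fit_logistic(cw_d, fixed_lapse = lapse)
    f2 <- fit_logistic(ccw_d, fixed_lapse = lapse)
    row <- tibble(duration_ms = d, pse_cw = f1$pse, pse_ccw = f2$pse,
                  tae_deg = pse_difference(f1, f2),
                  n_trials = nrow(cw_d) + nrow(ccw_d))
    if (n_resamples > 0) {
      mc <- monte_carlo_pse_test(cw_d, ccw_d, n_resamples = n_resamples,
                                 seed = seed, lapse = lapse)
      row$p_value <- mc$p_value
    }
    row
  })
  catch <- if (any(as.logical(trials$is_catch))) {
    catch_visibility(trials)
  }
  list(lapse = lapse, by_duration = by_dur, catch = catch)
}
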