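#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit>",
      if (!is.null(x$condition)) paste0("[", x$condition, "]"), "\n")
  cat(sprintf("  PSE = %.3f deg, slope = %.3f /deg, lapse = %.4f%s\n",
              x$pse, x$slope, x$lapse,
              if (x$lapse_fixed) " (fixed)" else ""))
  cat(sprintf("  %d trials at %d offsets, logLik = %.2f\n",
              x$n_trials, nrow(x$data), x$logLik))
  invisible(x)
}

#' Tidy a psychometric fit
#'
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`pse`, `slope`,
#'   `lapse`) and columns `term`, `estimate`, `fixed`.
#' @method tidy psychometric_fit
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble(term = c("pse", "slope", "lapse"),
         estimate = c(x$pse, x$slope, x$lapse),
         fixed = c(FALSE, FALSE, x$lapse_fixed))
}

#' One-row summary of a psychometric fit
#'
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `pse`, `slope`, `lapse`, `n_trials`,
#'   `n_offsets`, `logLik`.
#' @method glance psychometric_fit
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble(pse = x$pse, slope = x$slope, lapse = x$lapse,
         n_trials = x$n_trials, n_offsets = nrow(x$data),
         logLik = x$logLik)
}

#' Predicted clockwise-response probability
#'
#' @param object A `psychometric_fit`.
#' @param newdata Optional vector of test offsets (degrees); defaults
#'   to the fitted offsets.
#' @param ... Unused.
#' @return Probabilities in `[lapse, 1 - lapse]`.
#' @export
predict.psychometric_fit <- function(object, newdata = NULL, ...) {
  x <- newdata %||% object$data$x
  psychometric_prob(x, object$pse, object$slope, object$lapse)
}

#' Bootstrap confidence interval for the PSE
#'
#' Percentile interval from the parametric-bootstrap PSE samples
#' attached by `fit_logistic(..., n_boot = )`.
#'
#' @param object A `psychometric_fit` fitted with `n_boot > 0`.
#' @param parm Unused (only the PSE is resampled).
#' @param level Confidence level.
#' @param ... Unused.
#' @return A 1 x 2 matrix of interval endpoints.
#' @export
confint.psychometric_fit <- function(object, parm = "pse", level = 0.95,
                                     ...) {
  if (is.null(object$boot_pse) || !length(object$boot_pse)) {
    stop_domain("No bootstrap samples: refit with `n_boot > 0`.")
  }
  a <- (1 - level) / 2
  ci <- quantile(object$boot_pse, c(a, 1 - a), names = FALSE)
  matrix(ci, nrow = 1,
         dimnames = list("pse", sprintf("%.1f %%", 100 * c(a, 1 - a))))
}
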