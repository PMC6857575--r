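#' Generative observer parameters
#'
#' The synthetic observer answers the two-alternative forced-choice
#' ("which side is tilted more clockwise?") according to the same
#' lapse-padded logistic the analysis fits, with its PSE displaced by
#' an adaptation-dependent attractive shift.  The shift is
#' per-condition: fitting clockwise- and counterclockwise-adapter
#' trials separately and differencing the PSEs recovers `2 * shift`.
#'
#' @param pse_shift_by_duration Named numeric vector mapping test
#'   duration (ms, as names) to the per-condition attractive PSE shift
#'   in degrees (positive = toward the adapter).
#' @param slope Psychometric slope, per degree, `> 0`.
#' @param lapse Lapse rate in `[0, 0.2]`.
#' @param catch_visibility Probability excess (over 0.5) with which
#'   catch-trial responses are consistent with the adapter-reference
#'   relation; 0 (the default) makes catch responses coin flips.
#' @return An object of class `observer_params`.
#' @examples
#' observer_params(c(`50` = 2, `100` = 0.5, `200` = 0), slope = 0.5)
#' @export
observer_params <- function(pse_shift_by_duration, slope = 0.5,
                            lapse = 0.02, catch_visibility = 0) {
  if (is.null(names(pse_shift_by_duration)) ||
      any(!nzchar(names(pse_shift_by_duration)))) {
    stop_domain("`pse_shift_by_duration` must be named by duration in ms.")
  }
  if (slope <= 0) stop_domain("`slope` must be positive.")
  if (lapse < 0 || lapse > 0.2) stop_domain("`lapse` must lie in [0, 0.2].")
  if (catch_visibility < -0.5 || catch_visibility > 0.5) {
    stop_domain("`catch_visibility` must lie in [-0.5, 0.5].")
  }
  structure(list(pse_shift_by_duration = pse_shift_by_duration,
                 slope = slope, lapse = lapse,
                 catch_visibility = catch_visibility),
            class = "observer_params")
}

#' Session design for the short-term adaptation paradigm
#'
#' Encodes the trial structure of the brief-adapter experiment: a
#' fresh uniformly random adapter orientation on every trial (so
#' orientation-specific effects cannot accumulate across trials), a
#' reference offset of +/- 17-23 degrees (uniform jitter around the
#' +/-20 degrees that maximizes the tuning-shift effect), test
#' durations interleaved in equal proportion, 10% catch trials, and
#' test-minus-reference offsets from a constant-stimuli grid.
#'
#' @param n_trials Total trial count.
#' @param durations Test durations, ms.
#' @param ref_offset_range Magnitude range of the reference offset,
#'   degrees.
#' @param catch_fraction Fraction of catch trials.
#' @param test_offsets Constant-stimuli grid of test offsets, degrees.
#' @param subject Subject label.
#' @return An object of class `session_design`.
#' @export
session_design <- function(n_trials = 1000,
                           durations = c(50, 100, 200),
                           ref_offset_range = c(17, 23),
                           catch_fraction = 0.10,
                           test_offsets = seq(-12, 12, by = 4),
                           subject = "synthetic") {
  if (n_trials < 1) stop_domain("`n_trials` must be positive.")
  if (catch_fraction < 0 || catch_fraction >= 1) {
    stop_domain("`catch_fraction` must lie in [0, 1).")
  }
  structure(list(n_trials = as.integer(n_trials), durations = durations,
                 ref_offset_range = ref_offset_range,
                 catch_fraction = catch_fraction,
                 test_offsets = test_offsets, subject = subject),
            class = "session_design")
}

#' Generate a synthetic session of adaptation trials
#'
#' Draws a full trial table from the design and observer.  The
#' pseudo-random stream is consumed in a fixed, vectorized column
#' order — duration shuffle, catch flags, adapter orientations,
#' reference-offset signs, reference-offset magnitudes, test offsets,
#' response uniforms — so the table is reproducible from the seed.
#' On non-catch trials the clockwise-response probability is
#' `lapse + (1 - 2 lapse) * logistic(slope * (x - sign(ref_offset) * shift(duration)))`,
#' which makes the fitted clockwise-minus-counterclockwise PSE
#' difference equal `2 * shift` in expectation.  Catch trials are
#' answered consistently with the adapter-reference relation with
#' probability `0.5 + catch_visibility`.
#'
#' @param design A [session_design()].
#' @param observer An [observer_params()].
#' @param seed Integer seed; the caller's RNG stream is left
#'   untouched.
#' @return A tibble with columns `subject`, `adapter_deg`,
#'   `ref_offset_deg`, `test_offset_deg` (`NA` on catch trials),
#'   `duration_ms`, `is_catch`, `response_cw`.
#' @examples
#' s <- generate_session(session_design(n_trials = 20),
#'                       observer_params(c(`50` = 2, `100` = 1, `200` = 0)),
#'                       seed = 1)
#' @export
generate_session <- function(design, observer, seed = 1L) {
  stopifnot(inherits(design, "session_design"),
            inherits(observer, "observer_params"))
  shifts <- observer$pse_shift_by_duration
  missing <- setdiff(as.character(design$durations), names(shifts))
  if (length(missing)) {
    stop_domain(paste0("No PSE shift specified for duration(s) ",
                       paste(missing, collapse = ", "), " ms."))
  }
  n <- design$n_trials
  withr::with_seed(seed, {
    duration <- sample(rep_len(design$durations, n))
    is_catch <- runif(n) < design$catch_fraction
    adapter <- runif(n, 0, 180)
    ro_sign <- sample(c(-1, 1), n, replace = TRUE)
    ro_mag <- runif(n, design$ref_offset_range[1], design$ref_offset_range[2])
    test_offset <- sample(design$test_offsets, n, replace = TRUE)
    u <- runif(n)

    ref_offset <- ro_sign * ro_mag
    shift <- unname(shifts[as.character(duration)])
    p_cw <- psychometric_prob(test_offset, ro_sign * shift,
                              observer$slope, observer$lapse)
    response <- u < p_cw
    # catch trials: consistent with the adapter-reference relation
    # (adapter clockwise of reference <=> ref_offset < 0) with
    # probability 0.5 + visibility
    consistent <- u < 0.5 + observer$catch_visibility
    response[is_catch] <- (consistent == (ref_offset < 0))[is_catch]
    test_offset[is_catch] <- NA_real_

    tibble(subject = design$subject, adapter_deg = adapter,
           ref_offset_deg = ref_offset, test_offset_deg = test_offset,
           duration_ms = duration, is_catch = is_catch,
           response_cw = response)
  })
}

#' Observer whose adaptation follows a model prediction
#'
#' Closes the model-to-behavior loop: the per-condition PSE shift at
#' each test duration is set to half the model-predicted TAE at that
#' time after test onset, so the expected fitted TAE-versus-duration
#' curve of the synthetic observer equals the model's prediction.
#'
#' @param pred A `tae_prediction` from [predict_tae()].
#' @param durations Test durations, ms, at which the prediction is
#'   read out.
#' @param slope,lapse,catch_visibility Forwarded to
#'   [observer_params()].
#' @param mode Readout mode for [tae_at()].
#' @return An [observer_params()] object.
#' @export
model_linked_observer <- function(pred, durations = c(50, 100, 200),
                                  slope = 0.5, lapse = 0.02,
                                  catch_visibility = 0,
                                  mode = "instantaneous") {
  shifts <- tae_at(pred, durations, mode = mode) / 2
  observer_params(setNames(shifts, as.character(durations)),
                  slope = slope, lapse = lapse,
                  catch_visibility = catch_visibility)
}

#' Read or write a trial table
#'
#' Plain-CSV serialization of trial records with the canonical header
#' `subject, adapter_deg, ref_offset_deg, test_offset_deg, duration_ms,
#' is_catch, response_cw`.
#'
#' @param path File path.
#' @return `read_trials()` returns a tibble; `write_trials()` returns
#'   `path` invisibly.
#' @export
read_trials <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject = readr::col_character(),
    adapter_deg = readr::col_double(),
    ref_offset_deg = readr::col_double(),
    test_offset_deg = readr::col_double(),
    duration_ms = readr::col_double(),
    is_catch = readr::col_logical(),
    response_cw = readr::col_logical()
  ))
}

#' @rdname read_trials
#' @param trials Trial table.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}
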