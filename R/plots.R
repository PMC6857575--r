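#' Plot a population rate trajectory
#'
#' Heat map of firing rate over time and preferred orientation — the
#' travelling hill of population activity.
#'
#' @param object A `ring_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ring_trajectory
#' @export
autoplot.ring_trajectory <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$time_ms, .data$preferred_deg,
                               fill = .data$rate_hz)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "rate (Hz)") +
    ggplot2::labs(x = "time (ms)", y = "preferred orientation (deg)") +
    ggplot2::theme_minimal()
}

#' Plot a decoded-orientation trace
#'
#' @param object A `decoded_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decoded_trace
#' @export
autoplot.decoded_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$decoded_deg)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (ms)", y = "decoded orientation (deg)") +
    ggplot2::theme_minimal()
}

#' Plot a predicted TAE time course
#'
#' @param object A `tae_prediction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tae_prediction
#' @export
autoplot.tae_prediction <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$tae_deg)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after test onset (ms)", y = "predicted TAE (deg)",
                  title = paste0("suppression: ", attr(object, "variant"))) +
    ggplot2::theme_minimal()
}

#' Plot a psychometric fit
#'
#' Observed clockwise-response proportions (point size by trial count)
#' with the fitted lapse-padded logistic.
#'
#' @param object A `psychometric_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psychometric_fit
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  agg <- dplyr::mutate(object$data, prop = .data$k / .data$n)
  grid <- tibble(x = seq(min(agg$x), max(agg$x), length.out = 200))
  grid$p <- predict(object, grid$x)
  ggplot2::ggplot(agg, ggplot2::aes(.data$x, .data$prop)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$x, .data$p)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$pse, linetype = 2,
                        colour = "grey60") +
    ggplot2::scale_size_area(name = "trials") +
    ggplot2::labs(x = "test - reference offset (deg)",
                  y = "P(respond clockwise)") +
    ggplot2::theme_minimal()
}
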