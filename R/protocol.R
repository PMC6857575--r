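#' Stimulus protocols
#'
#' A stimulus protocol is an ordered sequence of epochs, each holding a
#' single oriented stimulus at fixed contrast for a fixed duration.
#' The feedforward drive is constant within an epoch and switches
#' instantaneously at epoch boundaries (no afferent delay is modelled).
#'
#' @param orientation_deg Stimulus orientation per epoch, degrees;
#'   reduced modulo 180 on construction.
#' @param contrast Contrast per epoch, `>= 0`; recycled.
#' @param duration_ms Epoch duration, ms, `> 0`.
#' @param label Optional free-text label stored as an attribute.
#' @return A tibble of class `stimulus_protocol` with columns
#'   `orientation_deg`, `contrast`, `duration_ms`.
#' @examples
#' stimulus_protocol(c(20, 0), 1, c(200, 500), label = "adapt-then-test")
#' @export
stimulus_protocol <- function(orientation_deg, contrast = 1, duration_ms,
                              label = NULL) {
  if (length(orientation_deg) < 1) stop_domain("A protocol needs at least one epoch.")
  n <- length(orientation_deg)
  contrast <- rep_len(contrast, n)
  duration_ms <- rep_len(duration_ms, n)
  if (any(!is.finite(duration_ms)) || any(duration_ms <= 0)) {
    stop_domain("Epoch durations must be positive and finite.")
  }
  if (any(contrast < 0)) stop_domain("Contrasts must be non-negative.")
  out <- tibble(orientation_deg = orientation_deg %% 180,
                contrast = contrast, duration_ms = duration_ms)
  class(out) <- c("stimulus_protocol", class(out))
  attr(out, "label") <- label
  out
}

#' Total protocol duration in ms
#' @param protocol A [stimulus_protocol()].
#' @return Scalar, ms.
#' @export
protocol_duration <- function(protocol) sum(protocol$duration_ms)

#' Read network parameters and a protocol from a YAML config
#'
#' The config is a plain-text YAML file with a `network` mapping (any
#' subset of the [network_params()] arguments) and an optional
#' `protocol` list of epochs with fields `orientation`, `contrast`,
#' `duration`.  The bundled default config reproduces the published
#' parameter set and the adapt-then-test protocol:
#' `system.file("extdata", "default_network.yaml", package = "ringtae")`.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `params` ([network_params()]) and
#'   `protocol` (a [stimulus_protocol()] or `NULL`).
#' @export
read_network_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- do.call(network_params, cfg$network %||% list())
  protocol <- NULL
  if (!is.null(cfg$protocol)) {
    eps <- purrr::transpose(cfg$protocol)
    protocol <- stimulus_protocol(
      orientation_deg = as.numeric(unlist(eps$orientation)),
      contrast = as.numeric(unlist(eps$contrast %||% rep(1, length(eps$orientation)))),
      duration_ms = as.numeric(unlist(eps$duration)),
      label = cfg$label %||% NULL
    )
  }
  list(params = params, protocol = protocol)
}
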