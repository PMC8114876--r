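#' Drifting-grating stimulus protocol
#'
#' Describes the stimulus grid and timing under which trial responses are
#' collected: a set of grating drift directions crossed with a set of temporal
#' frequencies at a single spatial frequency, each condition repeated a fixed
#' number of times, plus stimulus-free blank sweeps.  The default protocol is
#' a 2 s grating followed by a 1 s mean-luminance gray period, eight directions
#' at 45 degree spacing, temporal frequencies of 1, 2, 4, 8 and 15 Hz at
#' 0.04 cycles/degree, and 15 trials per condition.
#'
#' @param directions Grating drift directions in degrees; distinct values in
#'   `[0, 360)`.
#' @param temporal_frequencies Temporal frequencies in Hz; distinct positive
#'   values.
#' @param spatial_frequency Spatial frequency in cycles/degree (metadata only;
#'   the grid has a single spatial frequency).
#' @param n_trials_per_condition Number of repeats of each grating condition
#'   (at least 2).
#' @param n_blank_sweeps Number of blank (mean-luminance gray) sweeps.
#' @param stimulus_duration_s Grating presentation duration in seconds.
#' @param gray_duration_s Pre-stimulus gray period in seconds; this window is
#'   the per-trial baseline.
#' @param sampling_rate_hz Sampling rate used when synthesising dF/F traces.
#'
#' @return An object of class `grating_protocol`.
#' @export
#' @examples
#' p <- grating_protocol()
#' nrow(protocol_conditions(p))  # 8 directions x 5 TFs = 40
grating_protocol <- function(directions = seq(0, 315, by = 45),
                             temporal_frequencies = c(1, 2, 4, 8, 15),
                             spatial_frequency = 0.04,
                             n_trials_per_condition = 15,
                             n_blank_sweeps = 15,
                             stimulus_duration_s = 2,
                             gray_duration_s = 1,
                             sampling_rate_hz = 30) {
  directions <- as.numeric(directions)
  temporal_frequencies <- as.numeric(temporal_frequencies)
  if (anyDuplicated(directions) || any(directions < 0 | directions >= 360)) {
    stop("directions must be distinct angles in [0, 360)", call. = FALSE)
  }
  if (anyDuplicated(temporal_frequencies) || any(temporal_frequencies <= 0)) {
    stop("temporal_frequencies must be distinct and > 0", call. = FALSE)
  }
  if (n_trials_per_condition < 2) {
    stop("n_trials_per_condition must be >= 2", call. = FALSE)
  }
  if (stimulus_duration_s <= 0 || gray_duration_s <= 0 || sampling_rate_hz <= 0) {
    stop("durations and sampling rate must be > 0", call. = FALSE)
  }
  structure(
    list(
      directions = sort(directions),
      temporal_frequencies = sort(temporal_frequencies),
      spatial_frequency = spatial_frequency,
      n_trials_per_condition = as.integer(n_trials_per_condition),
      n_blank_sweeps = as.integer(n_blank_sweeps),
      stimulus_duration_s = stimulus_duration_s,
      gray_duration_s = gray_duration_s,
      sampling_rate_hz = sampling_rate_hz
    ),
    class = "grating_protocol"
  )
}

#' @export
print.grating_protocol <- function(x, ...) {
  cat("Drifting-grating protocol\n")
  cat("  directions (deg):", paste(x$directions, collapse = ", "), "\n")
  cat("  temporal frequencies (Hz):",
      paste(x$temporal_frequencies, collapse = ", "), "\n")
  cat("  spatial frequency (cpd):", x$spatial_frequency, "\n")
  cat("  trials/condition:", x$n_trials_per_condition,
      " blank sweeps:", x$n_blank_sweeps, "\n")
  cat("  timing: ", x$gray_duration_s, "s gray + ",
      x$stimulus_duration_s, "s grating @ ", x$sampling_rate_hz, " Hz\n",
      sep = "")
  invisible(x)
}

#' Condition grid of a protocol
#'
#' Grating conditions in the canonical order used throughout the package:
#' direction-major, temporal frequency fastest-varying within a direction.
#' Argmax ties over this ordering therefore resolve to the smallest direction
#' first, then the smallest temporal frequency.
#'
#' @param protocol A [grating_protocol()].
#' @return A tibble with columns `direction_deg` and `tf_hz`, one row per
#'   grating condition.
#' @export
protocol_conditions <- function(protocol) {
  stopifnot(inherits(protocol, "grating_protocol"))
  tibble::tibble(
    direction_deg = rep(protocol$directions,
                        each = length(protocol$temporal_frequencies)),
    tf_hz = rep(protocol$temporal_frequencies, length(protocol$directions))
  )
}

n_gray_samples <- function(protocol) {
  round(protocol$gray_duration_s * protocol$sampling_rate_hz)
}

n_stim_samples <- function(protocol) {
  round(protocol$stimulus_duration_s * protocol$sampling_rate_hz)
}

#' @keywords internal
opposite_direction_index <- function(directions) {
  opp <- (directions + 180) %% 360
  idx <- match(opp, directions)
  idx
}
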