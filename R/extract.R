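#' Reduce a single-trial dF/F trace to its summary statistics
#'
#' The trace is assumed to cover the gray (baseline) period immediately
#' followed by the stimulus period at the protocol sampling rate.  The evoked
#' response is the mean dF/F over the stimulus window; the evoked max is the
#' maximum over the same window; baseline mean and SD are taken over the gray
#' period immediately preceding stimulus onset.  Windows are half-open at the
#' sample level so they are disjoint and tile the trace.
#'
#' @param trace Numeric dF/F vector, gray period then stimulus period.
#' @param protocol A [grating_protocol()].
#' @return A one-row tibble with columns `evoked_mean_dff`, `evoked_max_dff`,
#'   `baseline_mean_dff`, `baseline_sd_dff`.
#' @export
#' @examples
#' p <- grating_protocol()
#' extract_trial(rep(0.1, 90), p)  # constant trace
extract_trial <- function(trace, protocol) {
  stopifnot(inherits(protocol, "grating_protocol"))
  ng <- n_gray_samples(protocol)
  ns <- n_stim_samples(protocol)
  if (length(trace) < ng + ns) {
    stop("malformed trace: ", length(trace), " samples, protocol window needs ",
         ng + ns, call. = FALSE)
  }
  base <- trace[seq_len(ng)]
  stim <- trace[ng + seq_len(ns)]
  tibble::tibble(
    evoked_mean_dff = mean(stim),
    evoked_max_dff = max(stim),
    baseline_mean_dff = mean(base),
    baseline_sd_dff = stats::sd(base)
  )
}

#' Mean evoked response over the trials of one condition
#'
#' The arithmetic mean of the per-trial evoked mean dF/F, i.e. the
#' trial-averaged response used for preferred-condition identification and
#' every tuning metric.
#'
#' @param trials Numeric vector of per-trial evoked means, or a data frame
#'   with an `evoked_mean_dff` column.
#' @return The mean evoked dF/F (fraction).
#' @export
mean_evoked_response <- function(trials) {
  x <- if (is.data.frame(trials)) trials$evoked_mean_dff else trials
  if (length(x) == 0) stop("missing data: no trials supplied", call. = FALSE)
  mean(x)
}

#' Extract trial summaries from a long table of trace samples
#'
#' Accepts externally supplied traces in long form (one row per sample) and
#' emits one trial-response row per trial.  Blank sweeps are rows whose
#' `direction_deg` and `tf_hz` are both missing.
#'
#' @param samples A data frame with columns `cell_id`, `area`, `direction_deg`,
#'   `tf_hz`, `trial_index`, `sample_index`, `dff`.
#' @param protocol A [grating_protocol()] describing the per-trial window.
#' @return A response table (one row per trial).
#' @export
extract_trials <- function(samples, protocol) {
  need <- c("cell_id", "area", "direction_deg", "tf_hz", "trial_index",
            "sample_index", "dff")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  samples |>
    dplyr::arrange(.data$cell_id, .data$direction_deg, .data$tf_hz,
                   .data$trial_index, .data$sample_index) |>
    dplyr::group_by(.data$cell_id, .data$area, .data$direction_deg,
                    .data$tf_hz, .data$trial_index) |>
    dplyr::reframe(extract_trial(.data$dff, protocol)) |>
    tibble::as_tibble()
}
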