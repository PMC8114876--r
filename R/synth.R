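#' Configuration for a synthetic population
#'
#' Defines the sampling distributions for the generative parameters of every
#' cell in a simulated population.  The generative model for a responsive cell
#' is a separable tuning surface: a von Mises lobe in direction (with a
#' secondary lobe at the opposite direction whose relative height sets the
#' true direction selectivity) multiplied by a Gaussian in log2 temporal
#' frequency.  Noise is additive and Gaussian: per-sample fluctuation on the
#' trace (`baseline_sd`) plus a per-trial gain on the evoked response
#' (`noise_sd`); dF/F may therefore go negative, as real dF/F does.
#'
#' Defaults emulate a layer 2/3 population under the default
#' [grating_protocol()]: most cells respond with peak mean dF/F of a few to a
#' few tens of percent with trial-to-trial variability of comparable order
#' (coefficients of variation around 0.3-1.5), and a configurable fraction is
#' unresponsive (pure noise).  Per-area octave shifts of the preferred-TF
#' distribution give higher areas distinct TF preferences so that rank-order
#' changes under selection can be exercised; the shift values are modelling
#' choices, not claims about the areas.
#'
#' @param n_cells_per_area Cells simulated in each area.
#' @param areas Character vector of area labels.
#' @param area_tf_bias Named numeric, octaves added to the mean of the log2
#'   preferred-TF sampling distribution per area.  Unnamed areas get 0.
#' @param fraction_unresponsive Proportion of cells with amplitude 0.
#' @param pref_tf_log2_mean,pref_tf_log2_sd Mean and SD (octaves) of the log2
#'   preferred-TF distribution before the area bias is added; samples are
#'   clamped to the protocol TF range at generation time.
#' @param amplitude_meanlog,amplitude_sdlog Log-normal parameters of the peak
#'   mean dF/F (fraction) of responsive cells.
#' @param kappa_range Uniform range of the von Mises direction concentration.
#' @param symmetry_range Uniform range of the opposite-lobe relative height in
#'   `[0, 1]` (1 = orientation-tuned, 0 = fully direction-selective).
#' @param tf_bandwidth_range Uniform range of the log2-Gaussian TF bandwidth
#'   in octaves.
#' @param noise_sd_range Uniform range of the per-trial gain SD (dF/F).
#' @param baseline_sd_range Uniform range of the per-sample trace noise SD.
#' @param seed Mandatory RNG seed; a config fully determines the population.
#'
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_cells_per_area = 100,
                              areas = c("V1", "LM", "AL", "PM", "AM", "RL"),
                              area_tf_bias = c(V1 = 0, LM = 0.2, AL = 1,
                                               PM = -0.5, AM = 0.5, RL = 0.3),
                              fraction_unresponsive = 0.3,
                              pref_tf_log2_mean = 1,
                              pref_tf_log2_sd = 1,
                              amplitude_meanlog = log(0.12),
                              amplitude_sdlog = 0.6,
                              kappa_range = c(1.5, 4),
                              symmetry_range = c(0, 0.8),
                              tf_bandwidth_range = c(1, 2),
                              noise_sd_range = c(0.02, 0.10),
                              baseline_sd_range = c(0.01, 0.03),
                              seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory in a population config", call. = FALSE)
  }
  if (n_cells_per_area < 1) stop("n_cells_per_area must be >= 1", call. = FALSE)
  if (fraction_unresponsive < 0 || fraction_unresponsive > 1) {
    stop("fraction_unresponsive must be in [0, 1]", call. = FALSE)
  }
  stopifnot(length(areas) >= 1, !anyDuplicated(areas))
  structure(
    list(
      n_cells_per_area = as.integer(n_cells_per_area),
      areas = as.character(areas),
      area_tf_bias = area_tf_bias,
      fraction_unresponsive = fraction_unresponsive,
      pref_tf_log2_mean = pref_tf_log2_mean,
      pref_tf_log2_sd = pref_tf_log2_sd,
      amplitude_meanlog = amplitude_meanlog,
      amplitude_sdlog = amplitude_sdlog,
      kappa_range = kappa_range,
      symmetry_range = symmetry_range,
      tf_bandwidth_range = tf_bandwidth_range,
      noise_sd_range = noise_sd_range,
      baseline_sd_range = baseline_sd_range,
      seed = as.integer(seed)
    ),
    class = "population_config"
  )
}

#' Expected evoked response of a ground-truth cell
#'
#' The noiseless tuning surface: amplitude times a direction factor (von Mises
#' lobe at the preferred direction plus a `direction_symmetry`-scaled lobe at
#' the opposite direction, normalised to 1 at the preferred direction) times a
#' Gaussian in log2 temporal frequency centred on the preferred TF.  The
#' surface is nonnegative everywhere and attains `amplitude` exactly at
#' `(pref_direction_deg, pref_tf_hz)`.
#'
#' @param cell A one-row data frame / list of ground-truth parameters with
#'   fields `pref_direction_deg`, `pref_tf_hz`, `direction_concentration`,
#'   `direction_symmetry`, `tf_bandwidth_oct`, `amplitude`.
#' @param direction Direction(s) in degrees.
#' @param tf Temporal frequency(ies) in Hz; must be > 0.
#' @return Expected mean evoked dF/F (fraction), vectorised over
#'   `direction`/`tf`.
#' @export
#' @examples
#' cell <- list(pref_direction_deg = 90, pref_tf_hz = 4,
#'              direction_concentration = 2, direction_symmetry = 0.5,
#'              tf_bandwidth_oct = 1.5, amplitude = 0.2)
#' expected_response(cell, 90, 4)   # == 0.2
expected_response <- function(cell, direction, tf) {
  if (any(!is.finite(tf)) || any(tf <= 0)) {
    stop("invalid stimulus: temporal frequency must be positive", call. = FALSE)
  }
  th <- (direction - cell$pref_direction_deg) * pi / 180
  k <- cell$direction_concentration
  s <- cell$direction_symmetry
  dir_fac <- exp(k * (cos(th) - 1)) + s * exp(k * (cos(th - pi) - 1))
  dir_fac <- dir_fac / (1 + s * exp(-2 * k))
  tf_fac <- exp(-(log2(tf) - log2(cell$pref_tf_hz))^2 /
                  (2 * cell$tf_bandwidth_oct^2))
  cell$amplitude * dir_fac * tf_fac
}

#' Simulate one trial's dF/F trace
#'
#' Returns the gray (baseline) period followed by the stimulus period at the
#' protocol sampling rate.  Every sample carries independent Gaussian noise of
#' SD `baseline_sd`; the stimulus period additionally carries the expected
#' evoked response plus a single per-trial Gaussian gain of SD `noise_sd`.
#' Blank sweeps (both `direction` and `tf` `NULL`/`NA`) have expected
#' response 0.
#'
#' @inheritParams expected_response
#' @param protocol A [grating_protocol()].
#' @param direction,tf Grating condition; both `NULL` (or `NA`) for a blank
#'   sweep.
#' @return Numeric vector of length
#'   `(gray_duration_s + stimulus_duration_s) * sampling_rate_hz`.
#' @export
simulate_trial_trace <- function(cell, protocol, direction = NULL, tf = NULL) {
  stopifnot(inherits(protocol, "grating_protocol"))
  blank <- is.null(direction) || is.null(tf) || is.na(direction) || is.na(tf)
  mu <- if (blank) 0 else expected_response(cell, direction, tf)
  ng <- n_gray_samples(protocol)
  ns <- n_stim_samples(protocol)
  gain <- if (cell$noise_sd > 0) stats::rnorm(1, 0, cell$noise_sd) else 0
  noise <- if (cell$baseline_sd > 0) {
    stats::rnorm(ng + ns, 0, cell$baseline_sd)
  } else {
    numeric(ng + ns)
  }
  c(noise[seq_len(ng)], mu + gain + noise[ng + seq_len(ns)])
}

sample_ground_truth <- function(config, protocol) {
  n_area <- config$n_cells_per_area
  areas <- rep(config$areas, each = n_area)
  n <- length(areas)
  bias <- config$area_tf_bias[areas]
  bias[is.na(bias)] <- 0
  tf_lim <- log2(range(protocol$temporal_frequencies))
  log2_tf <- stats::rnorm(n, config$pref_tf_log2_mean + bias,
                          config$pref_tf_log2_sd)
  log2_tf <- pmin(pmax(log2_tf, tf_lim[1]), tf_lim[2])
  amplitude <- stats::rlnorm(n, config$amplitude_meanlog, config$amplitude_sdlog)
  unresponsive <- stats::runif(n) < config$fraction_unresponsive
  amplitude[unresponsive] <- 0
  tibble::tibble(
    cell_id = sprintf("c%05d", seq_len(n)),
    area = areas,
    pref_direction_deg = stats::runif(n, 0, 360),
    pref_tf_hz = 2^log2_tf,
    direction_concentration = stats::runif(n, config$kappa_range[1],
                                           config$kappa_range[2]),
    direction_symmetry = stats::runif(n, config$symmetry_range[1],
                                      config$symmetry_range[2]),
    tf_bandwidth_oct = stats::runif(n, config$tf_bandwidth_range[1],
                                    config$tf_bandwidth_range[2]),
    amplitude = amplitude,
    noise_sd = stats::runif(n, config$noise_sd_range[1],
                            config$noise_sd_range[2]),
    baseline_sd = stats::runif(n, config$baseline_sd_range[1],
                               config$baseline_sd_range[2])
  )
}

#' Generate a synthetic population and its trial-response table
#'
#' Samples ground-truth tuning parameters for every cell, synthesises one
#' dF/F trace per cell x condition x trial (plus blank sweeps) under the
#' protocol timing, and reduces each trace to its trial summary (evoked mean
#' and max over the stimulus window; baseline mean and SD over the preceding
#' gray period).  Fully reproducible from `config$seed`.
#'
#' @param config A [population_config()].
#' @param protocol A [grating_protocol()].
#' @return A list with `trials` (the response table: one row per trial, see
#'   [read_response_table()] for the column contract) and `ground_truth` (one
#'   row per cell).
#' @export
#' @examples
#' pop <- generate_population(
#'   population_config(n_cells_per_area = 3, areas = c("V1", "AL"), seed = 1),
#'   grating_protocol(n_trials_per_condition = 3, n_blank_sweeps = 3)
#' )
#' dplyr::count(pop$trials, is_blank = is.na(direction_deg))
generate_population <- function(config, protocol = grating_protocol()) {
  stopifnot(inherits(config, "population_config"),
            inherits(protocol, "grating_protocol"))
  withr::with_seed(config$seed, {
    gt <- sample_ground_truth(config, protocol)
    conds <- protocol_conditions(protocol)
    ntr <- protocol$n_trials_per_condition
    nbl <- protocol$n_blank_sweeps
    ng <- n_gray_samples(protocol)
    ns <- n_stim_samples(protocol)
    n_cond <- nrow(conds)
    n_trial_tot <- n_cond * ntr + nbl

    # per-trial expected response, grating conditions then blanks
    dir_col <- c(rep(conds$direction_deg, each = ntr), rep(NA_real_, nbl))
    tf_col <- c(rep(conds$tf_hz, each = ntr), rep(NA_real_, nbl))
    trial_col <- c(rep(seq_len(ntr), n_cond), seq_len(nbl))

    res <- vector("list", nrow(gt))
    for (i in seq_len(nrow(gt))) {
      cell <- gt[i, ]
      mu_cond <- expected_response(cell, conds$direction_deg, conds$tf_hz)
      mu <- c(rep(mu_cond, each = ntr), rep(0, nbl))
      gain <- if (cell$noise_sd > 0) {
        stats::rnorm(n_trial_tot, 0, cell$noise_sd)
      } else {
        numeric(n_trial_tot)
      }
      # stimulus-window and gray-window samples, one column per trial
      stim <- matrix(stats::rnorm(ns * n_trial_tot, 0, cell$baseline_sd),
                     nrow = ns)
      stim <- sweep(stim, 2, mu + gain, "+")
      gray <- matrix(stats::rnorm(ng * n_trial_tot, 0, cell$baseline_sd),
                     nrow = ng)
      res[[i]] <- cbind(
        .colMeans(stim, ns, n_trial_tot),
        col_max(stim),
        .colMeans(gray, ng, n_trial_tot),
        col_sd(gray)
      )
    }
    stats_mat <- do.call(rbind, res)
    trials <- tibble::tibble(
      cell_id = rep(gt$cell_id, each = n_trial_tot),
      area = rep(gt$area, each = n_trial_tot),
      direction_deg = rep(dir_col, nrow(gt)),
      tf_hz = rep(tf_col, nrow(gt)),
      trial_index = rep(trial_col, nrow(gt)),
      evoked_mean_dff = stats_mat[, 1],
      evoked_max_dff = stats_mat[, 2],
      baseline_mean_dff = stats_mat[, 3],
      baseline_sd_dff = stats_mat[, 4]
    )
    list(trials = trials, ground_truth = gt)
  })
}

# column maxima / sample SDs of a matrix without apply() overhead
col_max <- function(m) {
  out <- m[1, ]
  if (nrow(m) > 1) for (i in 2:nrow(m)) out <- pmax(out, m[i, ])
  out
}

col_sd <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(0, ncol(m)))
  mu <- .colMeans(m, n, ncol(m))
  ss <- .colMeans(m^2, n, ncol(m))
  sqrt(pmax(ss - mu^2, 0) * n / (n - 1))
}
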