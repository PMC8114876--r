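# In-code fixtures: small balanced trial tables under the standard
# 8-direction x 5-TF grid.

grid_dirs <- seq(0, 315, by = 45)
grid_tfs <- c(1, 2, 4, 8, 15)

# Build one cell's trial table from a function f(direction, tf, trial_index)
# giving the evoked mean of each trial.  Blank sweeps get blank_f(trial).
toy_cell_trials <- function(f, ntr = 5, n_blank = 5,
                            blank_f = function(i) rep(0, length(i)),
                            baseline_mean = 0, baseline_sd = 0,
                            evoked_max_f = NULL,
                            cell_id = "c1", area = "V1") {
  if (is.null(evoked_max_f)) evoked_max_f <- f
  g <- expand.grid(tf_hz = grid_tfs, direction_deg = grid_dirs)
  rows <- lapply(seq_len(nrow(g)), function(i) {
    idx <- seq_len(ntr)
    tibble::tibble(
      cell_id = cell_id, area = area,
      direction_deg = g$direction_deg[i], tf_hz = g$tf_hz[i],
      trial_index = idx,
      evoked_mean_dff = f(g$direction_deg[i], g$tf_hz[i], idx),
      evoked_max_dff = evoked_max_f(g$direction_deg[i], g$tf_hz[i], idx),
      baseline_mean_dff = rep(baseline_mean, ntr),
      baseline_sd_dff = rep(baseline_sd, ntr)
    )
  })
  blanks <- tibble::tibble(
    cell_id = cell_id, area = area,
    direction_deg = NA_real_, tf_hz = NA_real_,
    trial_index = seq_len(n_blank),
    evoked_mean_dff = blank_f(seq_len(n_blank)),
    evoked_max_dff = blank_f(seq_len(n_blank)),
    baseline_mean_dff = rep(baseline_mean, n_blank),
    baseline_sd_dff = rep(baseline_sd, n_blank)
  )
  dplyr::bind_rows(c(rows, list(blanks)))
}

# A cell with a single peaked condition and a given null-direction response.
peaked_cell <- function(rpref, rnull = 0, pref_dir = 90, pref_tf = 4,
                        base = 0.01, ...) {
  toy_cell_trials(function(d, tf, i) {
    v <- if (d == pref_dir && tf == pref_tf) rpref
    else if (d == (pref_dir + 180) %% 360 && tf == pref_tf) rnull
    else base
    rep(v, length(i))
  }, ...)
}

# Random noisy multi-cell table (balanced), for oracle comparisons.
random_population_trials <- function(n_cells = 5, ntr = 6, n_blank = 6,
                                     sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_cells), function(k) {
      toy_cell_trials(
        function(d, tf, i) stats::rnorm(length(i), 0.05, sd),
        ntr = ntr, n_blank = n_blank,
        blank_f = function(i) stats::rnorm(length(i), 0, sd),
        cell_id = sprintf("c%03d", k)
      )
    }))
  })
}

# Independent tuning-metric oracles (trig sums / direct ratios), kept apart
# from the package's complex-arithmetic implementation.
oracle_osi <- function(r, dirs_deg) {
  th <- 2 * dirs_deg * pi / 180
  den <- sum(r)
  if (den <= 0) return(NA_real_)
  sqrt(sum(r * cos(th))^2 + sum(r * sin(th))^2) / den
}

oracle_dsi <- function(rpref, rnull) {
  if (rpref + rnull == 0) return(NA_real_)
  (rpref - rnull) / (rpref + rnull)
}

# Brute-force preferred condition: scan all conditions with tapply.
oracle_preferred <- function(trials) {
  g <- trials[!is.na(trials$direction_deg), ]
  cm <- tapply(g$evoked_mean_dff, list(g$direction_deg, g$tf_hz), mean)
  dirs <- as.numeric(rownames(cm))
  tfs <- as.numeric(colnames(cm))
  best <- which(cm == max(cm), arr.ind = TRUE)
  # lexicographic tie-break: smallest direction, then smallest TF
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  list(direction_deg = dirs[best[1, 1]], tf_hz = tfs[best[1, 2]])
}
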