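#' Direction selectivity index
#'
#' `DSI = (Rpref - Rnull) / (Rpref + Rnull)`, where `Rpref` is the mean
#' response at the preferred direction and `Rnull` the mean response at the
#' opposite direction (same temporal frequency).  No clipping is applied:
#' negative mean responses can push the index outside `[0, 1]` and such values
#' are returned as-is.  A zero denominator yields `NA` (undefined).
#'
#' @param rpref,rnull Mean evoked responses at the preferred and opposite
#'   (null) directions.
#' @return The index, vectorised; `NA` where `rpref + rnull == 0`.
#' @export
#' @examples
#' dsi_index(0.2, 0)    # 1: inevitable when the null response is 0
#' dsi_index(0.3, 0.1)  # 0.5
dsi_index <- function(rpref, rnull) {
  den <- rpref + rnull
  out <- (rpref - rnull) / den
  out[den == 0] <- NA_real_
  out
}

#' Global orientation selectivity index
#'
#' The vector-sum measure `|sum(R_theta * exp(2i * theta))| / sum(R_theta)`
#' over the direction responses at one temporal frequency; the angle doubling
#' folds opposite drift directions onto a single orientation.  A nonpositive
#' denominator yields `NA` (undefined).
#'
#' @param responses Mean evoked responses, one per direction.
#' @param directions_deg Directions in degrees, same length as `responses`.
#' @return The index, or `NA` if `sum(responses) <= 0`.
#' @export
#' @examples
#' global_osi(rep(1, 8), seq(0, 315, by = 45))                    # 0
#' global_osi(c(1, .5, 0, .5, 1, .5, 0, .5), seq(0, 315, by = 45)) # 0.5
global_osi <- function(responses, directions_deg) {
  stopifnot(length(responses) == length(directions_deg))
  den <- sum(responses)
  if (!is.finite(den) || den <= 0) return(NA_real_)
  Mod(sum(responses * exp(2i * directions_deg * pi / 180))) / den
}

#' Octave-scale mean of temporal frequencies
#'
#' Preferred temporal frequencies are averaged on a base-2 logarithmic
#' (octave) scale and converted back to Hz, respecting the logarithmic
#' spacing of the stimulus grid: `2^mean(log2(tf))`.
#'
#' @param tfs Positive temporal frequencies in Hz.
#' @return The octave-scale mean in Hz.
#' @export
#' @examples
#' mean_pref_tf(c(1, 4))  # 2
mean_pref_tf <- function(tfs) {
  if (length(tfs) == 0) stop("missing data: no TFs supplied", call. = FALSE)
  if (any(tfs <= 0)) stop("TFs must be > 0", call. = FALSE)
  2^mean(log2(tfs))
}

cell_condition_means <- function(trials) {
  validate_response_table(trials)
  g <- trials[!is.na(trials$direction_deg), ]
  if (nrow(g) == 0) stop("no grating trials for cell", call. = FALSE)
  g |>
    dplyr::group_by(.data$direction_deg, .data$tf_hz) |>
    dplyr::summarise(
      mean_response = mean(.data$evoked_mean_dff),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$direction_deg, .data$tf_hz)
}

#' Preferred condition of one cell
#'
#' The grating condition (direction, TF) that evoked the largest mean
#' response.  Ties are broken deterministically: smallest direction first,
#' then smallest temporal frequency.  Every grid condition must be present.
#'
#' @param trials One cell's trial rows (response-table columns).
#' @return A list with `direction_deg`, `tf_hz` and `mean_response`.
#' @export
preferred_condition <- function(trials) {
  cm <- cell_condition_means(trials)
  dirs <- unique(cm$direction_deg)
  tfs <- unique(cm$tf_hz)
  if (nrow(cm) != length(dirs) * length(tfs)) {
    stop("missing data: incomplete direction x TF grid", call. = FALSE)
  }
  i <- which.max(cm$mean_response)
  list(direction_deg = cm$direction_deg[i], tf_hz = cm$tf_hz[i],
       mean_response = cm$mean_response[i])
}

#' Direction selectivity of one cell's trials
#'
#' @param trials One cell's trial rows.
#' @param pref Optional preferred condition (as from [preferred_condition()]);
#'   computed from the trials when omitted.
#' @return DSI (see [dsi_index()]); `NA` when undefined.
#' @export
dsi <- function(trials, pref = NULL) {
  if (is.null(pref)) pref <- preferred_condition(trials)
  cm <- cell_condition_means(trials)
  null_dir <- (pref$direction_deg + 180) %% 360
  rp <- cm$mean_response[cm$direction_deg == pref$direction_deg &
                           cm$tf_hz == pref$tf_hz]
  rn <- cm$mean_response[cm$direction_deg == null_dir & cm$tf_hz == pref$tf_hz]
  if (length(rp) != 1 || length(rn) != 1) {
    stop("missing data: preferred or opposite condition absent", call. = FALSE)
  }
  dsi_index(rp, rn)
}

#' Global orientation selectivity of one cell's trials
#'
#' @param trials One cell's trial rows.
#' @param pref_tf Temporal frequency at which to take the direction responses;
#'   defaults to the cell's preferred TF.
#' @return Global OSI (see [global_osi()]); `NA` when undefined.
#' @export
osi <- function(trials, pref_tf = NULL) {
  if (is.null(pref_tf)) pref_tf <- preferred_condition(trials)$tf_hz
  cm <- cell_condition_means(trials)
  at_tf <- cm[cm$tf_hz == pref_tf, ]
  dirs <- sort(unique(cm$direction_deg))
  if (nrow(at_tf) != length(dirs)) {
    stop("missing data: not all directions present at the preferred TF",
         call. = FALSE)
  }
  global_osi(at_tf$mean_response, at_tf$direction_deg)
}

#' Coefficient of variation at the preferred condition
#'
#' The ratio of the sample SD (denominator `n - 1`) of the per-trial evoked
#' responses at the preferred condition to their mean.  A low CV indicates a
#' robust response.  A nonpositive mean yields `NA` (undefined); undefined
#' cells rank least robust downstream.
#'
#' @param trials One cell's trial rows.
#' @param pref Optional preferred condition; computed when omitted.
#' @return SD/mean at the preferred condition, or `NA`.
#' @export
response_cv <- function(trials, pref = NULL) {
  if (is.null(pref)) pref <- preferred_condition(trials)
  x <- trials$evoked_mean_dff[
    !is.na(trials$direction_deg) &
      trials$direction_deg == pref$direction_deg &
      trials$tf_hz == pref$tf_hz
  ]
  if (length(x) < 2) stop("need >= 2 trials at the preferred condition",
                          call. = FALSE)
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  stats::sd(x) / m
}

# metrics for one cell slice of a prepared population
plain_cell_metrics <- function(m, blanks, prep) {
  cm <- .colMeans(m, nrow(m), ncol(m))
  p <- which.max(cm)
  rp <- cm[p]
  oppc <- prep$opp_cond[p]
  d <- if (is.na(oppc)) NA_real_ else dsi_index(rp, cm[oppc])
  tfi <- ((p - 1L) %% prep$ntf) + 1L
  o <- global_osi(cm[prep$tf_groups[[tfi]]], prep$dirs)
  x <- m[, p]
  sp <- stats::sd(x)
  cv <- if (rp <= 0) NA_real_ else sp / rp
  rel <- NA_real_
  if (!is.null(blanks)) {
    rb <- mean(blanks)
    sb <- stats::sd(blanks)
    num <- rp - rb
    den <- sp + sb
    rel <- if (den == 0) {
      if (num > 0) Inf else if (num < 0) -Inf else NaN
    } else num / den
  }
  list(pref = p, pref_dir = prep$cond_dir[p], pref_tf = prep$cond_tf[p],
       osi = o, dsi = d, cv = cv, reliability = rel, cond_means = cm)
}

cv_cell_metrics <- function(m, prep, splits) {
  n_iter <- length(splits)
  dsi_it <- osi_it <- tf_it <- rpref_it <- numeric(n_iter)
  dir_it <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    sel <- splits[[it]]$sel
    est <- splits[[it]]$est
    cmA <- .colMeans(m[sel, , drop = FALSE], length(sel), ncol(m))
    cmB <- .colMeans(m[est, , drop = FALSE], length(est), ncol(m))
    p <- which.max(cmA)
    oppc <- prep$opp_cond[p]
    dsi_it[it] <- if (is.na(oppc)) NA_real_ else dsi_index(cmB[p], cmB[oppc])
    tfi <- ((p - 1L) %% prep$ntf) + 1L
    osi_it[it] <- global_osi(cmB[prep$tf_groups[[tfi]]], prep$dirs)
    tf_it[it] <- prep$cond_tf[p]
    dir_it[it] <- prep$cond_dir[p]
    rpref_it[it] <- cmB[p]
  }
  # cross-validated CV: variability of the held-out preferred response across
  # iterations relative to its mean; shrinks with trial count as the
  # estimate stabilises
  rp_mean <- mean(rpref_it)
  cv_cross <- if (rp_mean <= 0 || n_iter < 2) NA_real_ else
    stats::sd(rpref_it) / rp_mean
  # preferred direction reported as the modal half-A preference
  # (smallest direction on ties); preferred TF averaged on the octave scale
  tab <- tabulate(match(dir_it, prep$dirs), nbins = prep$ndir)
  list(
    pref_dir = prep$dirs[which.max(tab)],
    pref_tf = 2^mean(log2(tf_it)),
    osi = if (all(is.na(osi_it))) NA_real_ else mean(osi_it, na.rm = TRUE),
    dsi = if (all(is.na(dsi_it))) NA_real_ else mean(dsi_it, na.rm = TRUE),
    cv_crossval = cv_cross,
    n_undef_osi = sum(is.na(osi_it)),
    n_undef_dsi = sum(is.na(dsi_it)),
    n_undef_cv = as.integer(is.na(cv_cross))
  )
}

make_cv_splits <- function(ntr, n_iter) {
  k <- floor(ntr / 2)
  lapply(seq_len(n_iter), function(i) {
    perm <- sample.int(ntr)
    list(sel = perm[seq_len(k)], est = perm[(k + 1):ntr])
  })
}

metrics_from_prep <- function(prep, mode, n_iter) {
  ncell <- prep$ncell
  out <- tibble::tibble(
    cell_id = prep$cell_id, area = prep$area,
    pref_direction_deg = NA_real_, pref_tf_hz = NA_real_,
    osi = NA_real_, dsi = NA_real_, cv = NA_real_, reliability = NA_real_,
    mode = mode, n_trials_used = prep$ntr,
    cv_crossval = NA_real_,
    n_undefined_osi = 0L, n_undefined_dsi = 0L, n_undefined_cv = 0L
  )
  splits <- if (mode == "cv") make_cv_splits(prep$ntr, n_iter) else NULL
  for (i in seq_len(ncell)) {
    m <- prep$ev[, , i]
    bl <- if (is.null(prep$blanks)) NULL else prep$blanks[, i]
    pl <- plain_cell_metrics(m, bl, prep)
    out$cv[i] <- pl$cv
    out$reliability[i] <- pl$reliability
    if (mode == "plain") {
      out$pref_direction_deg[i] <- pl$pref_dir
      out$pref_tf_hz[i] <- pl$pref_tf
      out$osi[i] <- pl$osi
      out$dsi[i] <- pl$dsi
      out$n_undefined_osi[i] <- as.integer(is.na(pl$osi))
      out$n_undefined_dsi[i] <- as.integer(is.na(pl$dsi))
    } else {
      cvm <- cv_cell_metrics(m, prep, splits)
      out$pref_direction_deg[i] <- cvm$pref_dir
      out$pref_tf_hz[i] <- cvm$pref_tf
      out$osi[i] <- cvm$osi
      out$dsi[i] <- cvm$dsi
      out$cv_crossval[i] <- cvm$cv_crossval
      out$n_undefined_osi[i] <- cvm$n_undef_osi
      out$n_undefined_dsi[i] <- cvm$n_undef_dsi
      out$n_undefined_cv[i] <- cvm$n_undef_cv
    }
  }
  out
}

#' Per-cell tuning metrics for a population
#'
#' Computes, for every cell in a response table, the preferred condition,
#' DSI, global OSI, coefficient of variation and blank-sweep reliability.
#' In `"plain"` mode all trials are used both to identify the preferred
#' condition and to compute the metrics.  In `"cv"` mode the trials of each
#' condition are split in half (`floor(n/2)` selection trials, the remainder
#' estimation trials): the selection half identifies the preferred condition,
#' the estimation half yields the metric values at that condition, and the
#' results are averaged over `n_iter` random splits (preferred TF on the
#' octave scale; undefined iterations are dropped and counted in
#' `n_undefined_*`).  CV and reliability are always computed from all trials
#' at the plain preferred condition.
#'
#' The same random split is used for every condition and cell within an
#' iteration; trials are exchangeable, so this costs nothing statistically
#' and makes each cell's result independent of which other cells are in the
#' table.  Cross-validation requires a balanced table (equal trials per
#' condition).
#'
#' @param trials A response table (one row per trial; see
#'   [read_response_table()] for columns).
#' @param mode `"plain"` or `"cv"`.
#' @param n_iter Number of cross-validation iterations (default 50).
#' @param seed Optional seed making the cross-validation splits reproducible;
#'   `NULL` uses the current RNG state.
#' In `"cv"` mode the column `cv_crossval` additionally holds the
#' cross-validated coefficient of variation: the SD across iterations of the
#' estimation-half mean response at the selection-half preferred condition,
#' divided by its mean across iterations (undefined when that mean is
#' nonpositive).  It measures the stability of the cross-validated response
#' estimate and shrinks as more trials are available; trial-count sweeps
#' summarise this quantity.
#'
#' @return A tibble with one row per cell: `cell_id`, `area`,
#'   `pref_direction_deg`, `pref_tf_hz`, `osi`, `dsi`, `cv`, `reliability`,
#'   `mode`, `n_trials_used`, `cv_crossval`, `n_undefined_osi`,
#'   `n_undefined_dsi`, `n_undefined_cv`.
#' @export
compute_metrics <- function(trials, mode = c("plain", "cv"), n_iter = 50,
                            seed = NULL) {
  mode <- match.arg(mode)
  prep <- prepare_population(trials)
  if (mode == "cv" && prep$ntr < 2) {
    stop("insufficient trials: cross-validation needs >= 2 trials/condition",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    withr::with_seed(seed, metrics_from_prep(prep, mode, n_iter))
  } else {
    metrics_from_prep(prep, mode, n_iter)
  }
}

#' Cross-validated metrics for one cell
#'
#' Convenience wrapper over [compute_metrics()] for a single cell's trials.
#'
#' @param trials One cell's trial rows.
#' @inheritParams compute_metrics
#' @return A one-row metrics tibble (see [compute_metrics()]).
#' @export
cross_validated_metrics <- function(trials, n_iter = 50, seed = NULL) {
  compute_metrics(trials, mode = "cv", n_iter = n_iter, seed = seed)
}

#' Metrics under trial subsampling
#'
#' Draws `n_trials` trials per condition without replacement (the same trial
#' positions for every condition and cell; trials are exchangeable) and
#' applies the cross-validated metric computation to the subsample.  The CV
#' column is the plain coefficient of variation computed on the subsample at
#' the subsample's preferred condition, as used in trial-count sweeps.
#'
#' @param trials A response table.
#' @param n_trials Trials per condition to retain (`2 <= n_trials <=`
#'   available).
#' @inheritParams compute_metrics
#' @return A metrics tibble (see [compute_metrics()]) with
#'   `n_trials_used = n_trials`.
#' @export
subsampled_metrics <- function(trials, n_trials, n_iter = 50, seed = NULL) {
  run <- function() {
    prep <- prepare_population(trials)
    if (n_trials < 2 || n_trials > prep$ntr) {
      stop("insufficient trials: n_trials must be in [2, ", prep$ntr, "]",
           call. = FALSE)
    }
    if (n_trials < prep$ntr) {
      keep <- sort(sample.int(prep$ntr, n_trials))
      prep$ev <- prep$ev[keep, , , drop = FALSE]
      if (!is.null(prep$blanks)) {
        nb <- nrow(prep$blanks)
        keep_b <- sort(sample.int(nb, min(n_trials, nb)))
        prep$blanks <- prep$blanks[keep_b, , drop = FALSE]
      }
      prep$ntr <- n_trials
    }
    out <- metrics_from_prep(prep, "cv", n_iter)
    out$n_trials_used <- n_trials
    out
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Sweep the number of trials used per condition
#'
#' For each trial count `n` in `n_grid`, subsamples `n` trials per condition
#' and recomputes the cross-validated metrics on the subsample, then
#' summarises the population: mean cross-validated CV (`mean_cv`; see
#' [compute_metrics()]), mean plain subsample CV (`mean_cv_plain`), mean OSI,
#' mean DSI and octave-scale mean preferred TF (undefined values excluded,
#' counts reported), overall and per area.
#'
#' @param trials A response table.
#' @param n_grid Integer vector of trial counts (default `4:14`).
#' @inheritParams compute_metrics
#' @return A tibble with one row per (`n_trials`, area), area `"all"` being
#'   the pooled population.
#' @export
trial_count_sweep <- function(trials, n_grid = 4:14, n_iter = 50,
                              seed = NULL) {
  run <- function() {
    out <- lapply(n_grid, function(n) {
      met <- subsampled_metrics(trials, n, n_iter = n_iter)
      summarise_sweep(met, n)
    })
    dplyr::bind_rows(out)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

summarise_sweep <- function(met, n) {
  one <- function(df, label) {
    tibble::tibble(
      n_trials = n, area = label, n_cells = nrow(df),
      mean_cv = mean(df$cv_crossval, na.rm = TRUE),
      mean_cv_plain = mean(df$cv, na.rm = TRUE),
      mean_osi = mean(df$osi, na.rm = TRUE),
      mean_dsi = mean(df$dsi, na.rm = TRUE),
      mean_pref_tf_hz = mean_pref_tf(df$pref_tf_hz),
      n_cv_undefined = sum(is.na(df$cv_crossval)),
      n_dsi_undefined = sum(is.na(df$dsi)),
      n_osi_undefined = sum(is.na(df$osi))
    )
  }
  dplyr::bind_rows(
    one(met, "all"),
    dplyr::bind_rows(lapply(split(met, met$area), function(d) one(d, d$area[1])))
  )
}
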