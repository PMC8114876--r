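#' Rank cells from most to least robust
#'
#' Stable ascending order by coefficient of variation; cells with undefined
#' CV (nonpositive mean preferred response) are placed after all finite CVs,
#' and ties are broken by `cell_id`, so the ordering is total and
#' deterministic.
#'
#' @param metrics A per-cell metrics tibble (see [compute_metrics()]).
#' @return The same tibble, reordered.
#' @export
rank_by_cv <- function(metrics) {
  stopifnot(all(c("cell_id", "cv") %in% names(metrics)))
  metrics[order(is.na(metrics$cv), metrics$cv, metrics$cell_id,
                method = "radix"), ]
}

metric_column <- function(metric) {
  switch(metric,
         pref_tf = "pref_tf_hz",
         osi = "osi",
         dsi = "dsi",
         stop("unknown metric '", metric, "' (use pref_tf, osi or dsi)",
              call. = FALSE))
}

# mean and SEM of a metric over a set of cells; preferred TF is summarised on
# the octave scale (mean back-transformed to Hz, SEM in octaves)
metric_mean_sem <- function(values, metric) {
  v <- values[!is.na(values)]
  n_excluded <- sum(is.na(values))
  if (length(v) == 0) {
    return(list(mean = NA_real_, sem = NA_real_, n = 0, n_excluded = n_excluded))
  }
  if (metric == "pref_tf") {
    lg <- log2(v)
    list(mean = 2^mean(lg),
         sem = stats::sd(lg) / sqrt(length(lg)),
         n = length(v), n_excluded = n_excluded)
  } else {
    list(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
         n = length(v), n_excluded = n_excluded)
  }
}

#' Inclusion curve of a tuning metric
#'
#' Population mean (and SEM) of a metric in one area as a function of the
#' percentage of most-robust (lowest-CV) cells included.  For each percentage
#' `p` the `ceiling(p/100 * n_area)` lowest-CV cells are selected; at 100%
#' the curve equals the unconditional area mean exactly.  Preferred TF is
#' averaged on the octave scale; undefined metric values are excluded and
#' counted.
#'
#' @param metrics A per-cell metrics tibble.
#' @param area Area label to restrict to; `NULL` pools all cells.
#' @param metric One of `"pref_tf"`, `"osi"`, `"dsi"`.
#' @param percent_grid Increasing percentages in (0, 100]; default 5 to 100
#'   in steps of 5 (the smallest percentage shown is 5%).
#' @return A tibble with one row per percentage: `area`, `metric`, `percent`,
#'   `n_cells`, `mean_value`, `sem_value`, `n_excluded`, `mode`.
#' @export
inclusion_curve <- function(metrics, area = NULL, metric = "pref_tf",
                            percent_grid = seq(5, 100, by = 5)) {
  col <- metric_column(metric)
  if (is.unsorted(percent_grid, strictly = TRUE) ||
      any(percent_grid <= 0 | percent_grid > 100)) {
    stop("percent_grid must be strictly increasing within (0, 100]",
         call. = FALSE)
  }
  df <- if (is.null(area)) metrics else metrics[metrics$area == area, ]
  if (nrow(df) == 0) stop("missing data: no cells for area", call. = FALSE)
  df <- rank_by_cv(df)
  mode <- if ("mode" %in% names(df)) df$mode[1] else NA_character_
  rows <- lapply(percent_grid, function(p) {
    k <- ceiling(p / 100 * nrow(df))
    ms <- metric_mean_sem(df[[col]][seq_len(k)], metric)
    tibble::tibble(
      area = if (is.null(area)) "all" else area, metric = metric,
      percent = p, n_cells = k, mean_value = ms$mean, sem_value = ms$sem,
      n_excluded = ms$n_excluded, mode = mode
    )
  })
  dplyr::bind_rows(rows)
}

#' Metric values in a robustness decile
#'
#' The `ceiling(n/10)` most-robust (`which = "top"`, lowest CV) or
#' least-robust (`which = "bottom"`, highest CV including undefined) cells,
#' with a histogram of the chosen metric.
#'
#' @param metrics A per-cell metrics tibble (>= 10 cells).
#' @param metric One of `"pref_tf"`, `"osi"`, `"dsi"`.
#' @param which `"top"` (most robust) or `"bottom"` (least robust).
#' @param breaks Histogram break specification passed to [graphics::hist()];
#'   preferred TF is binned on the log2 scale.
#' @return A list with `values` (metric values of the decile, `NA` kept),
#'   `cells` (their ids), `counts`, `breaks` and `n_excluded` (undefined
#'   values left out of the histogram).
#' @export
decile_distribution <- function(metrics, metric = "dsi",
                                which = c("top", "bottom"), breaks = 20) {
  which <- match.arg(which)
  col <- metric_column(metric)
  if (nrow(metrics) < 10) stop("need >= 10 cells for deciles", call. = FALSE)
  ranked <- rank_by_cv(metrics)
  k <- ceiling(nrow(ranked) / 10)
  sel <- if (which == "top") ranked[seq_len(k), ]
         else ranked[seq(nrow(ranked) - k + 1, nrow(ranked)), ]
  v <- sel[[col]]
  vv <- v[!is.na(v)]
  if (metric == "pref_tf") vv <- log2(vv)
  h <- if (length(vv) > 0) {
    graphics::hist(vv, breaks = breaks, plot = FALSE)
  } else {
    list(counts = integer(0), breaks = numeric(0))
  }
  list(values = v, cells = sel$cell_id, counts = h$counts, breaks = h$breaks,
       n_excluded = sum(is.na(v)))
}

#' Select cells matching a target mean CV
#'
#' Returns the `N` lowest-CV cells of one area whose mean CV is closest to
#' `target_mean_cv`, found by exhaustive search over all prefixes of the CV
#' ranking (prefix means increase monotonically from the minimum CV to the
#' whole-area mean, so the optimum is within one prefix step).  Cells with
#' undefined CV cannot contribute to a mean and are excluded from the search.
#' Targets outside the achievable range return the nearest endpoint with a
#' warning.
#'
#' @param metrics A per-cell metrics tibble.
#' @param area Area label; `NULL` pools all cells.
#' @param target_mean_cv Target mean CV.
#' @return The selected rows of `metrics`, with attributes
#'   `achieved_mean_cv` and `n_selected`.
#' @export
cv_matched_selection <- function(metrics, area = NULL, target_mean_cv) {
  df <- if (is.null(area)) metrics else metrics[metrics$area == area, ]
  df <- df[!is.na(df$cv), ]
  if (nrow(df) == 0) stop("missing data: no cells with defined CV",
                          call. = FALSE)
  df <- rank_by_cv(df)
  prefix_mean <- cumsum(df$cv) / seq_len(nrow(df))
  if (target_mean_cv < prefix_mean[1] ||
      target_mean_cv > prefix_mean[length(prefix_mean)]) {
    warning("target mean CV ", signif(target_mean_cv, 4),
            " outside achievable range [", signif(prefix_mean[1], 4), ", ",
            signif(prefix_mean[length(prefix_mean)], 4),
            "]; returning nearest endpoint", call. = FALSE)
  }
  n <- which.min(abs(prefix_mean - target_mean_cv))
  out <- df[seq_len(n), ]
  attr(out, "achieved_mean_cv") <- prefix_mean[n]
  attr(out, "n_selected") <- n
  out
}

#' Compare the most-robust decile with the entire population
#'
#' Two-sided Mann-Whitney U test per area between the metric values of the
#' 10% most-robust cells and those of the entire population of that area
#' (the decile included, as the comparison is usually reported).  The default
#' significance threshold Bonferroni-corrects 0.05 over the number of areas.
#'
#' @param metrics A per-cell metrics tibble.
#' @param metric One of `"pref_tf"`, `"osi"`, `"dsi"`.
#' @param threshold Significance threshold; default `0.05 / n_areas`.
#' @return A tibble with one row per area: `area`, `metric`, `n_decile`,
#'   `n_all`, `statistic`, `p_value`, `significant`.  Degenerate groups give
#'   `NA` (undefined test).
#' @export
compare_top_decile_vs_all <- function(metrics, metric = "pref_tf",
                                      threshold = NULL) {
  col <- metric_column(metric)
  areas <- sort(unique(metrics$area))
  if (is.null(threshold)) threshold <- 0.05 / length(areas)
  rows <- lapply(areas, function(a) {
    df <- rank_by_cv(metrics[metrics$area == a, ])
    k <- ceiling(nrow(df) / 10)
    top <- df[[col]][seq_len(k)]
    all_v <- df[[col]]
    top <- top[!is.na(top)]
    all_v <- all_v[!is.na(all_v)]
    if (length(top) < 2 || length(all_v) < 2) {
      w <- list(statistic = NA_real_, p.value = NA_real_)
    } else if (length(unique(c(top, all_v))) == 1) {
      # complete ties: no evidence of a shift, maximal p
      w <- list(statistic = length(top) * length(all_v) / 2, p.value = 1)
    } else {
      w <- suppressWarnings(stats::wilcox.test(top, all_v, exact = FALSE))
    }
    tibble::tibble(
      area = a, metric = metric, n_decile = length(top), n_all = length(all_v),
      statistic = unname(w$statistic), p_value = w$p.value,
      significant = isTRUE(w$p.value < threshold)
    )
  })
  dplyr::bind_rows(rows)
}

#' Criterion-selected versus CV-matched tuning means
#'
#' For every (criterion, area) pair: the mean of a tuning metric over the
#' criterion-selected cells, and over a population of the area's lowest-CV
#' cells chosen to match the criterion-selected cells' mean CV (via
#' [cv_matched_selection()]).  The Pearson correlation across all pairs
#' measures how much of the criterion's effect on the population mean is
#' explained by response robustness alone.  Preferred TF means are
#' octave-scale means (reported in Hz).
#'
#' @param metrics A per-cell metrics tibble.
#' @param mask A criterion mask from [apply_criteria()].
#' @param metrics_list Which metrics to compare.
#' @return A list with `pairs` (tibble: criterion, area, metric, n_selected,
#'   target_mean_cv, achieved_mean_cv, mean_criterion_selected,
#'   mean_cv_matched) and `correlations` (tibble: metric, pearson_r,
#'   n_pairs).
#' @export
matched_vs_criterion_correlation <- function(metrics, mask,
                                             metrics_list = c("pref_tf", "osi",
                                                              "dsi")) {
  stopifnot(all(metrics$cell_id %in% mask$cell_id) ||
              all(mask$cell_id %in% metrics$cell_id))
  studies <- paste0("pass_study", 1:5)
  df <- dplyr::inner_join(metrics, mask[c("cell_id", studies)], by = "cell_id")
  areas <- sort(unique(df$area))
  rows <- list()
  for (st in studies) {
    for (a in areas) {
      in_area <- df[df$area == a, ]
      sel <- in_area[in_area[[st]], ]
      if (nrow(sel) == 0) next
      target <- mean(sel$cv, na.rm = TRUE)
      if (!is.finite(target)) next
      matched <- suppressWarnings(
        cv_matched_selection(in_area, area = NULL, target_mean_cv = target)
      )
      for (m in metrics_list) {
        col <- metric_column(m)
        rows[[length(rows) + 1]] <- tibble::tibble(
          criterion = st, area = a, metric = m,
          n_selected = nrow(sel),
          n_matched = nrow(matched),
          target_mean_cv = target,
          achieved_mean_cv = attr(matched, "achieved_mean_cv"),
          mean_criterion_selected = metric_mean_sem(sel[[col]], m)$mean,
          mean_cv_matched = metric_mean_sem(matched[[col]], m)$mean
        )
      }
    }
  }
  pairs <- dplyr::bind_rows(rows)
  cors <- lapply(metrics_list, function(m) {
    d <- pairs[pairs$metric == m, ]
    d <- d[is.finite(d$mean_criterion_selected) & is.finite(d$mean_cv_matched), ]
    r <- if (nrow(d) < 2 || stats::sd(d$mean_criterion_selected) == 0 ||
             stats::sd(d$mean_cv_matched) == 0) {
      NA_real_
    } else {
      stats::cor(d$mean_criterion_selected, d$mean_cv_matched)
    }
    tibble::tibble(metric = m, pearson_r = r, n_pairs = nrow(d))
  })
  list(pairs = pairs, correlations = dplyr::bind_rows(cors))
}
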