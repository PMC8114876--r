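#' Five published responsiveness inclusion criteria
#'
#' Each criterion classifies one cell as responsive (included) or not, from
#' its trial-response rows.  Thresholds are strict inequalities and dF/F is a
#' fraction (0.10 = 10%).
#'
#' * **Study 1** — mean evoked response at the preferred condition > 10% dF/F.
#' * **Study 2** — in at least 50% of preferred-condition trials the evoked
#'   response exceeds both the trial's baseline mean + 3 x baseline SD and
#'   5% dF/F.
#' * **Study 3** — paired t test between the preferred-condition trial
#'   responses and the blank-sweep responses, significant at
#'   `alpha / n_tests` (Bonferroni over the grating conditions; default
#'   0.05/40).  Trials are paired by index; unequal counts are truncated to
#'   the shorter.
#' * **Study 4** — some condition's mean response > 6% dF/F *and* reliability
#'   `(Rpref - Rblank) / (sigma_pref + sigma_blank) > 1`, where `Rblank` and
#'   `sigma_blank` are the mean and SD across blank sweeps.
#' * **Study 5** — maximum dF/F during the stimulus window of any grating
#'   trial > 4%.
#'
#' @param trials One cell's trial rows (response-table columns, including
#'   blank sweeps where the criterion needs them).
#' @param alpha,n_tests Study 3 significance level and Bonferroni divisor.
#' @return A logical scalar.
#' @name inclusion-criteria
NULL

#' @rdname inclusion-criteria
#' @export
study1 <- function(trials) {
  pref <- preferred_condition(trials)
  pref$mean_response > 0.10
}

#' @rdname inclusion-criteria
#' @export
study2 <- function(trials) {
  pref <- preferred_condition(trials)
  at <- trials[!is.na(trials$direction_deg) &
                 trials$direction_deg == pref$direction_deg &
                 trials$tf_hz == pref$tf_hz, ]
  ok <- at$evoked_mean_dff > at$baseline_mean_dff + 3 * at$baseline_sd_dff &
    at$evoked_mean_dff > 0.05
  mean(ok) >= 0.5
}

#' @rdname inclusion-criteria
#' @export
study3 <- function(trials, alpha = 0.05, n_tests = 40) {
  pref <- preferred_condition(trials)
  x <- trials$evoked_mean_dff[!is.na(trials$direction_deg) &
                                trials$direction_deg == pref$direction_deg &
                                trials$tf_hz == pref$tf_hz]
  b <- trials$evoked_mean_dff[is.na(trials$direction_deg)]
  if (length(b) == 0) stop("Study 3 requires blank sweeps", call. = FALSE)
  res <- paired_t(x, b)
  isTRUE(res$p < alpha / n_tests)
}

# paired t test by trial index, truncated to the shorter vector; constant
# nonzero differences count as arbitrarily significant, constant zero as null
paired_t <- function(x, b) {
  n <- min(length(x), length(b))
  d <- x[seq_len(n)] - b[seq_len(n)]
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd == 0) {
    if (mean(d) != 0) return(list(t = sign(mean(d)) * Inf, p = 0))
    return(list(t = NaN, p = 1))
  }
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

#' @rdname inclusion-criteria
#' @export
study4 <- function(trials) {
  pref <- preferred_condition(trials)
  cm <- cell_condition_means(trials)
  b <- trials$evoked_mean_dff[is.na(trials$direction_deg)]
  if (length(b) == 0) stop("Study 4 requires blank sweeps", call. = FALSE)
  x <- trials$evoked_mean_dff[!is.na(trials$direction_deg) &
                                trials$direction_deg == pref$direction_deg &
                                trials$tf_hz == pref$tf_hz]
  rel <- reliability_score(mean(x), mean(b), stats::sd(x), stats::sd(b))
  max(cm$mean_response) > 0.06 && isTRUE(rel > 1)
}

reliability_score <- function(rpref, rblank, sd_pref, sd_blank) {
  num <- rpref - rblank
  den <- sd_pref + sd_blank
  if (den == 0) {
    if (num > 0) return(Inf)
    if (num < 0) return(-Inf)
    return(NaN)
  }
  num / den
}

#' @rdname inclusion-criteria
#' @export
study5 <- function(trials) {
  mx <- trials$evoked_max_dff[!is.na(trials$direction_deg)]
  if (length(mx) == 0) stop("no grating trials", call. = FALSE)
  max(mx) > 0.04
}

#' Apply all five inclusion criteria to a population
#'
#' Evaluates every criterion for every cell of a response table, recording the
#' Study 3 and Study 4 intermediates (t statistic, p value, reliability
#' score).  Operates on the same balanced-table representation as
#' [compute_metrics()].
#'
#' @param trials A response table including blank sweeps.
#' @inheritParams inclusion-criteria
#' @return A tibble with one row per cell: `cell_id`, `area`,
#'   `pass_study1` ... `pass_study5`, `reliability_score`, `t_statistic`,
#'   `p_value`.
#' @seealso [criteria_overlap()] for per-criterion counts and the
#'   intersection-region accounting behind a Venn diagram.
#' @export
apply_criteria <- function(trials, alpha = 0.05, n_tests = 40) {
  prep <- prepare_population(trials)
  if (is.null(prep$bmean) || is.null(prep$bsd) || is.null(prep$evmax)) {
    stop("response table must carry evoked_max_dff and baseline columns",
         call. = FALSE)
  }
  if (is.null(prep$blanks)) {
    stop("criteria require blank sweeps in the table", call. = FALSE)
  }
  n <- prep$ncell
  out <- tibble::tibble(
    cell_id = prep$cell_id, area = prep$area,
    pass_study1 = NA, pass_study2 = NA, pass_study3 = NA,
    pass_study4 = NA, pass_study5 = NA,
    reliability_score = NA_real_, t_statistic = NA_real_, p_value = NA_real_
  )
  for (i in seq_len(n)) {
    m <- prep$ev[, , i]
    cm <- .colMeans(m, prep$ntr, prep$ncond)
    p <- which.max(cm)
    x <- m[, p]
    bl <- prep$blanks[, i]

    out$pass_study1[i] <- cm[p] > 0.10

    bm <- prep$bmean[, p, i]
    bs <- prep$bsd[, p, i]
    out$pass_study2[i] <- mean(x > bm + 3 * bs & x > 0.05) >= 0.5

    tt <- paired_t(x, bl)
    out$t_statistic[i] <- tt$t
    out$p_value[i] <- tt$p
    out$pass_study3[i] <- isTRUE(tt$p < alpha / n_tests)

    rel <- reliability_score(cm[p], mean(bl), stats::sd(x), stats::sd(bl))
    out$reliability_score[i] <- rel
    out$pass_study4[i] <- max(cm) > 0.06 && isTRUE(rel > 1)

    out$pass_study5[i] <- max(prep$evmax[, , i]) > 0.04
  }
  out
}

#' Overlap accounting for criterion masks
#'
#' Per-criterion selected counts and percentages, plus the count of every
#' intersection region of the five criteria (the regions of a 5-set Venn
#' diagram, keyed by a 5-character pass pattern such as `"10110"`).
#'
#' @param mask A criterion mask as returned by [apply_criteria()].
#' @return A list with `n_cells`, `per_criterion` (tibble: criterion, n,
#'   percent), `regions` (tibble: pattern, n), and `n_union`.
#' @export
criteria_overlap <- function(mask) {
  studies <- paste0("pass_study", 1:5)
  stopifnot(all(studies %in% names(mask)))
  pm <- as.matrix(mask[studies])
  per <- tibble::tibble(
    criterion = studies,
    n = colSums(pm),
    percent = 100 * colSums(pm) / nrow(pm)
  )
  pattern <- apply(pm * 1L, 1, paste, collapse = "")
  all_patterns <- apply(expand.grid(rep(list(1:0), 5))[, 5:1] * 1L, 1,
                        paste, collapse = "")
  counts <- table(factor(pattern, levels = all_patterns))
  regions <- tibble::tibble(pattern = names(counts), n = as.integer(counts))
  list(
    n_cells = nrow(pm),
    per_criterion = per,
    regions = regions,
    n_union = sum(rowSums(pm) > 0)
  )
}
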