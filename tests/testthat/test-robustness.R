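# small hand-built metrics tables
toy_metrics <- function(cv, dsi = NULL, osi = NULL, tf = NULL, area = "V1",
                        ids = NULL) {
  n <- length(cv)
  tibble::tibble(
    cell_id = if (is.null(ids)) sprintf("c%03d", seq_len(n)) else ids,
    area = rep_len(area, n),
    pref_direction_deg = 0,
    pref_tf_hz = if (is.null(tf)) rep(2, n) else tf,
    osi = if (is.null(osi)) stats::runif(n) else osi,
    dsi = if (is.null(dsi)) stats::runif(n) else dsi,
    cv = cv,
    reliability = 1,
    mode = "plain"
  )
}

test_that("cells rank from lowest to highest CV with undefined last", {
  m <- toy_metrics(c(0.5, 0.1, 0.3))
  expect_identical(rank_by_cv(m)$cell_id, c("c002", "c003", "c001"))

  m <- toy_metrics(c(0.2, NA, 0.2, NA))
  r <- rank_by_cv(m)
  expect_identical(r$cell_id, c("c001", "c003", "c002", "c004"))

  # equal CVs: cell_id order
  m <- toy_metrics(rep(0.4, 4), ids = c("d", "b", "a", "c"))
  expect_identical(rank_by_cv(m)$cell_id, c("a", "b", "c", "d"))

  # random CVs match an independent sort
  cv <- withr::with_seed(5, stats::runif(50))
  m <- toy_metrics(cv)
  expect_identical(rank_by_cv(m)$cv, sort(cv))
})

test_that("inclusion curves reach the unconditional mean at 100%", {
  cv <- withr::with_seed(6, stats::runif(37))
  dsi <- withr::with_seed(7, stats::runif(37))
  tf <- withr::with_seed(8, sample(c(1, 2, 4, 8, 15), 37, replace = TRUE))
  m <- toy_metrics(cv, dsi = dsi, tf = tf)
  cur_d <- inclusion_curve(m, area = "V1", metric = "dsi")
  expect_equal(cur_d$mean_value[cur_d$percent == 100], mean(dsi), tolerance = 0)
  cur_t <- inclusion_curve(m, area = "V1", metric = "pref_tf")
  expect_equal(cur_t$mean_value[cur_t$percent == 100], 2^mean(log2(tf)),
               tolerance = 0)
  expect_identical(cur_d$n_cells[cur_d$percent == 100], 37)

  # every grid point reproducible by brute-force recomputation
  ranked_dsi <- dsi[order(cv)]
  for (i in seq_len(nrow(cur_d))) {
    k <- ceiling(cur_d$percent[i] / 100 * 37)
    expect_equal(cur_d$mean_value[i], mean(ranked_dsi[seq_len(k)]))
  }
})

test_that("a shared-TF robust core drifts toward the grid mean as inclusion grows", {
  # low-CV cells all prefer 2 Hz; high-CV cells prefer TFs spread over the grid
  n_low <- 40; n_high <- 160
  tf_high <- withr::with_seed(9, sample(c(1, 2, 4, 8, 15), n_high, replace = TRUE))
  m <- toy_metrics(
    cv = c(stats::runif(n_low, 0, 0.2), stats::runif(n_high, 0.5, 2)),
    tf = c(rep(2, n_low), tf_high)
  )
  cur <- inclusion_curve(m, area = "V1", metric = "pref_tf",
                         percent_grid = c(20, 100))
  expect_equal(cur$mean_value[1], 2)   # the robust 20% share one TF
  expect_gt(cur$mean_value[2], 2)      # drifts toward the octave grid mean
  expect_equal(cur$mean_value[2],
               2^mean(log2(c(rep(2, n_low), tf_high))))
})

test_that("decile selection uses ceiling counts and sums its histogram", {
  m <- toy_metrics(withr::with_seed(10, stats::runif(10)))
  d <- decile_distribution(m, metric = "dsi", which = "top")
  expect_length(d$values, 1)

  m <- toy_metrics(withr::with_seed(11, stats::runif(105)))
  d <- decile_distribution(m, metric = "osi", which = "bottom")
  expect_length(d$values, 11)
  expect_identical(sum(d$counts), 11L)
  # bottom decile holds the highest CVs
  expect_true(min(m$cv[m$cell_id %in% d$cells]) >=
                sort(m$cv, decreasing = TRUE)[11])
})

test_that("CV-matched selection finds the best prefix by exhaustive search", {
  cv <- withr::with_seed(12, sort(stats::runif(60)))
  m <- toy_metrics(cv)
  # whole-area mean: everything selected
  sel <- cv_matched_selection(m, target_mean_cv = mean(cv))
  expect_identical(nrow(sel), 60L)
  # minimum CV: single most-robust cell
  sel <- cv_matched_selection(m, target_mean_cv = min(cv))
  expect_identical(nrow(sel), 1L)
  expect_equal(attr(sel, "achieved_mean_cv"), min(cv))
  # arbitrary target: brute force over all prefixes
  target <- 0.37
  pm <- cumsum(cv) / seq_along(cv)
  best_n <- which.min(abs(pm - target))
  sel <- cv_matched_selection(m, target_mean_cv = target)
  expect_identical(nrow(sel), as.integer(best_n))
  expect_equal(attr(sel, "achieved_mean_cv"), pm[best_n])
  # out-of-range target warns and clamps
  expect_warning(cv_matched_selection(m, target_mean_cv = 10), "range")
})

test_that("decile-vs-population comparison matches a hand-computed U statistic", {
  m <- toy_metrics(withr::with_seed(13, stats::runif(40)),
                   dsi = withr::with_seed(14, stats::runif(40)))
  res <- compare_top_decile_vs_all(m, metric = "dsi")
  ranked <- rank_by_cv(m)
  top <- ranked$dsi[1:4]
  all_v <- ranked$dsi
  # U = number of (top, all) pairs where top wins (+1/2 for ties)
  U <- sum(outer(top, all_v, ">")) + 0.5 * sum(outer(top, all_v, "=="))
  expect_equal(unname(res$statistic), U)
  w <- stats::wilcox.test(top, all_v, exact = FALSE)
  expect_equal(res$p_value, w$p.value)

  # identical groups: maximal p
  m2 <- toy_metrics(stats::runif(20), dsi = rep(0.4, 20))
  res2 <- compare_top_decile_vs_all(m2, metric = "dsi")
  expect_gte(res2$p_value, 0.99)
  # a strongly shifted decile is detected
  m3 <- toy_metrics(c(stats::runif(5, 0, 0.1), stats::runif(45, 1, 2)),
                    dsi = c(rep(5, 5), withr::with_seed(15, stats::runif(45))))
  res3 <- compare_top_decile_vs_all(m3, metric = "dsi", threshold = 0.05 / 6)
  expect_lt(res3$p_value, 0.05 / 6)
  expect_true(res3$significant)
})

test_that("criterion-selected and CV-matched means correlate perfectly when they coincide", {
  # two areas whose criterion picks exactly the lowest-CV prefix
  mk <- function(area, n, off) {
    m <- toy_metrics(sort(stats::runif(n, 0.1, 1)),
                     dsi = seq(0.2, 0.8, length.out = n) + off, area = area,
                     ids = paste0(area, sprintf("%03d", seq_len(n))))
    m
  }
  withr::with_seed(16, {
    m <- dplyr::bind_rows(mk("V1", 30, 0), mk("AL", 30, 0.1))
  })
  mask <- tibble::tibble(cell_id = m$cell_id)
  for (st in paste0("pass_study", 1:5)) mask[[st]] <- FALSE
  # each study selects a different-sized lowest-CV prefix per area
  for (s in 1:5) {
    k <- 5 * s
    sel <- unlist(lapply(split(m, m$area), function(d) {
      rank_by_cv(d)$cell_id[seq_len(k)]
    }))
    mask[[paste0("pass_study", s)]] <- mask$cell_id %in% sel
  }
  out <- matched_vs_criterion_correlation(m, mask, metrics_list = "dsi")
  expect_equal(out$pairs$mean_criterion_selected, out$pairs$mean_cv_matched)
  expect_equal(out$correlations$pearson_r, 1)

  # constant means across pairs: undefined correlation sentinel
  m2 <- m
  m2$dsi <- 0.5
  out2 <- matched_vs_criterion_correlation(m2, mask, metrics_list = "dsi")
  expect_true(is.na(out2$correlations$pearson_r))
})
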