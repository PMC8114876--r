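# Internal: validate a response table and reshape it into per-cell arrays.
#
# The population engines (metrics, criteria) operate on a balanced design:
# every cell has the same full direction x TF grid with an equal number of
# trials per condition, as in the drifting-grating protocol (15 trials per
# condition).  Conditions are ordered direction-major with TF fastest-varying,
# so that a first-maximum argmax resolves ties to the smallest direction, then
# the smallest TF.

response_table_columns <- c(
  "cell_id", "area", "direction_deg", "tf_hz", "trial_index",
  "evoked_mean_dff", "evoked_max_dff", "baseline_mean_dff", "baseline_sd_dff"
)

validate_response_table <- function(trials, require_all = FALSE) {
  need <- c("cell_id", "direction_deg", "tf_hz", "trial_index",
            "evoked_mean_dff")
  if (require_all) need <- response_table_columns
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    stop("response table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- xor(is.na(trials$direction_deg), is.na(trials$tf_hz))
  if (any(bad)) {
    stop("blank sweeps must have direction_deg and tf_hz missing jointly (",
         sum(bad), " inconsistent row(s))", call. = FALSE)
  }
  invisible(trials)
}

prepare_population <- function(trials) {
  validate_response_table(trials)
  if (!("area" %in% names(trials))) trials$area <- "all"
  trials$direction_deg <- as.double(trials$direction_deg)
  trials$tf_hz <- as.double(trials$tf_hz)
  is_blank <- is.na(trials$direction_deg)
  g <- trials[!is_blank, ]
  b <- trials[is_blank, ]
  if (nrow(g) == 0) stop("no grating trials in table", call. = FALSE)

  dirs <- sort(unique(g$direction_deg))
  tfs <- sort(unique(g$tf_hz))
  ndir <- length(dirs)
  ntf <- length(tfs)
  ncond <- ndir * ntf

  ord <- order(g$cell_id, g$direction_deg, g$tf_hz, g$trial_index,
               method = "radix")
  g <- g[ord, ]
  cell_id <- unique(g$cell_id)
  ncell <- length(cell_id)
  if (nrow(g) %% (ncell * ncond) != 0) {
    stop("unbalanced response table: expected an equal number of trials for ",
         "every cell x condition", call. = FALSE)
  }
  ntr <- nrow(g) / (ncell * ncond)
  tmpl_dir <- rep(rep(dirs, each = ntf * ntr), ncell)
  tmpl_tf <- rep(rep(rep(tfs, each = ntr), ndir), ncell)
  if (!identical(g$direction_deg, tmpl_dir) || !identical(g$tf_hz, tmpl_tf)) {
    stop("unbalanced or incomplete response table: every cell must have the ",
         "full direction x TF grid with equal trial counts", call. = FALSE)
  }
  area <- g$area[seq(1, nrow(g), by = ncond * ntr)]

  ev <- array(g$evoked_mean_dff, dim = c(ntr, ncond, ncell))
  bmean <- bsd <- NULL
  if ("baseline_mean_dff" %in% names(g)) {
    bmean <- array(g$baseline_mean_dff, dim = c(ntr, ncond, ncell))
  }
  if ("baseline_sd_dff" %in% names(g)) {
    bsd <- array(g$baseline_sd_dff, dim = c(ntr, ncond, ncell))
  }
  evmax <- NULL
  if ("evoked_max_dff" %in% names(g)) {
    evmax <- array(g$evoked_max_dff, dim = c(ntr, ncond, ncell))
  }

  blanks <- NULL
  if (nrow(b) > 0) {
    ordb <- order(b$cell_id, b$trial_index, method = "radix")
    b <- b[ordb, ]
    if (nrow(b) %% ncell != 0 ||
        !identical(unique(b$cell_id), cell_id)) {
      stop("blank sweeps must be present in equal number for every cell",
           call. = FALSE)
    }
    blanks <- matrix(b$evoked_mean_dff, ncol = ncell)
  }

  cond_dir <- rep(dirs, each = ntf)
  cond_tf <- rep(tfs, ndir)
  opp_dir_idx <- opposite_direction_index(dirs)
  opp_cond <- ifelse(is.na(rep(opp_dir_idx, each = ntf)), NA_integer_,
                     (rep(opp_dir_idx, each = ntf) - 1L) * ntf +
                       rep(seq_len(ntf), ndir))
  tf_groups <- lapply(seq_len(ntf), function(t) seq(t, by = ntf, length.out = ndir))

  list(
    cell_id = cell_id, area = area, dirs = dirs, tfs = tfs,
    ndir = ndir, ntf = ntf, ncond = ncond, ncell = ncell, ntr = ntr,
    cond_dir = cond_dir, cond_tf = cond_tf, opp_cond = opp_cond,
    tf_groups = tf_groups,
    e2i = exp(2i * dirs * pi / 180),
    ev = ev, bmean = bmean, bsd = bsd, evmax = evmax, blanks = blanks
  )
}
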