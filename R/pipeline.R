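#' @importFrom dplyr .data
NULL

#' Read and write response tables
#'
#' The response-table CSV dialect: a header row; columns `cell_id`, `area`,
#' `direction_deg`, `tf_hz`, `trial_index`, `evoked_mean_dff`,
#' `evoked_max_dff`, `baseline_mean_dff`, `baseline_sd_dff`; one row per
#' trial; UTF-8 with `.` as the decimal separator.  Blank sweeps leave
#' `direction_deg` and `tf_hz` empty (jointly).  Values round-trip at 12
#' significant digits.
#'
#' @param trials A response table.
#' @param path File path.
#' @return `read_response_table()` returns the validated tibble;
#'   `write_response_table()` returns `path` invisibly.
#' @export
write_response_table <- function(trials, path) {
  validate_response_table(trials, require_all = TRUE)
  write_csv12(trials[response_table_columns], path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) {
  df <- read_csv_checked(path, response_table_columns)
  df$cell_id <- as.character(df$cell_id)
  df$area <- as.character(df$area)
  validate_response_table(df, require_all = TRUE)
  df
}

write_csv12 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) {
    out[[j]] <- formatC(df[[j]], digits = 12, format = "g")
    out[[j]][is.na(df[[j]])] <- ""
    # keep integers unmangled
    if (is.integer(df[[j]])) out[[j]] <- as.character(df[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Run configuration
#'
#' Bundles every knob of an end-to-end run; a config plus its master seed
#' fully determines every output byte.  The master seed spawns one
#' independent substream seed per stage (a documented fixed scheme:
#' `stage_seed = (master_seed * 48271 + k) mod (2^31 - 1)` for stage index
#' `k`), so stages can be rerun in isolation with identical results.
#'
#' @param protocol A [grating_protocol()].
#' @param population A [population_config()]; its seed is overridden by the
#'   generate-stage seed derived from `master_seed`.
#' @param n_cv_iterations Cross-validation iterations for cv-mode metrics.
#' @param alpha,bonferroni_n Study 3 parameters.
#' @param percent_grid Inclusion-curve percentage grid.
#' @param sweep_trials Trial counts for the trial-count sweep (`NULL`
#'   disables the sweep).
#' @param master_seed Master RNG seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(protocol = grating_protocol(),
                       population = NULL,
                       n_cv_iterations = 50,
                       alpha = 0.05,
                       bonferroni_n = NULL,
                       percent_grid = seq(5, 100, by = 5),
                       sweep_trials = 4:14,
                       master_seed = 1L) {
  if (is.null(population)) {
    population <- population_config(seed = master_seed)
  }
  if (is.null(bonferroni_n)) {
    bonferroni_n <- length(protocol$directions) *
      length(protocol$temporal_frequencies)
  }
  structure(
    list(protocol = protocol, population = population,
         n_cv_iterations = n_cv_iterations, alpha = alpha,
         bonferroni_n = bonferroni_n, percent_grid = percent_grid,
         sweep_trials = sweep_trials, master_seed = as.integer(master_seed)),
    class = "run_config"
  )
}

stage_seed <- function(master_seed, k) {
  as.integer((as.numeric(master_seed) * 48271 + k) %% (2^31 - 1))
}

#' Read or write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(
    protocol = unclass(config$protocol),
    population = unclass(config$population),
    n_cv_iterations = config$n_cv_iterations,
    alpha = config$alpha,
    bonferroni_n = config$bonferroni_n,
    percent_grid = config$percent_grid,
    sweep_trials = config$sweep_trials,
    master_seed = config$master_seed
  )
  x$population$area_tf_bias <- as.list(config$population$area_tf_bias)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  protocol <- do.call(grating_protocol, x$protocol)
  pop_args <- x$population
  pop_args$area_tf_bias <- unlist(pop_args$area_tf_bias)
  population <- do.call(population_config, pop_args)
  run_config(protocol = protocol, population = population,
             n_cv_iterations = x$n_cv_iterations, alpha = x$alpha,
             bonferroni_n = x$bonferroni_n,
             percent_grid = x$percent_grid,
             sweep_trials = x$sweep_trials,
             master_seed = x$master_seed)
}

#' Run the full analysis pipeline
#'
#' Chains generation, metric computation (plain and cross-validated),
#' inclusion criteria, overlap accounting, inclusion curves, decile
#' distributions, Mann-Whitney comparisons, CV-matched selection and the
#' trial-count sweep, writing every artifact to `out_dir`:
#'
#' * `trials.csv`, `ground_truth.csv`
#' * `metrics_plain.csv`, `metrics_cv.csv`
#' * `criteria_mask.csv`, `overlap_counts.json`
#' * `inclusion_curves.csv` (plain and cv modes, all areas x metrics)
#' * `decile_histograms.csv`
#' * `mann_whitney.csv`
#' * `matched_comparison.csv`, `matched_correlations.csv`
#' * `trial_sweep.csv` (if `sweep_trials` is set)
#' * `manifest.json` (seeds, stage log, excluded-cell counts)
#'
#' A stage failure aborts the run with an error naming the stage; nothing is
#' silently partial.  Two runs with the same config produce byte-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every in-memory artifact plus the manifest.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(
    generate = stage_seed(config$master_seed, 1),
    metrics_cv = stage_seed(config$master_seed, 2),
    sweep = stage_seed(config$master_seed, 3)
  )
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  pop_cfg <- config$population
  pop_cfg$seed <- seeds$generate
  pop <- stage("generate", generate_population(pop_cfg, config$protocol))
  log$n_cells <- nrow(pop$ground_truth)
  log$n_trials <- nrow(pop$trials)

  met_plain <- stage("metrics", compute_metrics(pop$trials, mode = "plain"))
  met_cv <- stage("metrics", compute_metrics(
    pop$trials, mode = "cv", n_iter = config$n_cv_iterations,
    seed = seeds$metrics_cv
  ))
  log$n_cv_undefined_plain <- sum(is.na(met_plain$cv))
  log$n_dsi_undefined_plain <- sum(is.na(met_plain$dsi))

  mask <- stage("criteria", apply_criteria(
    pop$trials, alpha = config$alpha, n_tests = config$bonferroni_n
  ))
  overlap <- stage("criteria", criteria_overlap(mask))
  log$n_selected_per_criterion <- stats::setNames(
    as.list(overlap$per_criterion$n), overlap$per_criterion$criterion
  )

  areas <- sort(unique(met_plain$area))
  metric_names <- c("pref_tf", "osi", "dsi")
  curves <- stage("curves", dplyr::bind_rows(lapply(
    list(met_plain, met_cv), function(met) {
      dplyr::bind_rows(lapply(areas, function(a) {
        dplyr::bind_rows(lapply(metric_names, function(m) {
          inclusion_curve(met, area = a, metric = m,
                          percent_grid = config$percent_grid)
        }))
      }))
    }
  )))

  deciles <- stage("deciles", dplyr::bind_rows(lapply(
    list(met_plain, met_cv), function(met) {
      dplyr::bind_rows(lapply(metric_names, function(m) {
        dplyr::bind_rows(lapply(c("top", "bottom"), function(w) {
          d <- decile_distribution(met, metric = m, which = w)
          tibble::tibble(
            mode = met$mode[1], metric = m, decile = w,
            bin_left = utils::head(d$breaks, -1),
            bin_right = d$breaks[-1], count = d$counts
          )
        }))
      }))
    }
  )))

  mw <- stage("mann_whitney", dplyr::bind_rows(lapply(metric_names, function(m) {
    compare_top_decile_vs_all(met_plain, metric = m)
  })))

  matched <- stage("matched", matched_vs_criterion_correlation(
    met_plain, mask, metrics_list = metric_names
  ))

  sweep <- NULL
  if (!is.null(config$sweep_trials)) {
    sweep <- stage("sweep", trial_count_sweep(
      pop$trials, n_grid = config$sweep_trials,
      n_iter = config$n_cv_iterations, seed = seeds$sweep
    ))
  }

  stage("write", {
    write_response_table(pop$trials, file.path(out_dir, "trials.csv"))
    write_csv12(pop$ground_truth, file.path(out_dir, "ground_truth.csv"))
    write_csv12(met_plain, file.path(out_dir, "metrics_plain.csv"))
    write_csv12(met_cv, file.path(out_dir, "metrics_cv.csv"))
    write_csv12(mask, file.path(out_dir, "criteria_mask.csv"))
    jsonlite::write_json(
      list(n_cells = overlap$n_cells,
           per_criterion = overlap$per_criterion,
           regions = overlap$regions,
           n_union = overlap$n_union),
      file.path(out_dir, "overlap_counts.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    write_csv12(curves, file.path(out_dir, "inclusion_curves.csv"))
    write_csv12(deciles, file.path(out_dir, "decile_histograms.csv"))
    write_csv12(mw, file.path(out_dir, "mann_whitney.csv"))
    write_csv12(matched$pairs, file.path(out_dir, "matched_comparison.csv"))
    write_csv12(matched$correlations,
                file.path(out_dir, "matched_correlations.csv"))
    if (!is.null(sweep)) {
      write_csv12(sweep, file.path(out_dir, "trial_sweep.csv"))
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("driftmetrics")),
      master_seed = config$master_seed,
      stage_seeds = seeds,
      log = log
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(list(
    trials = pop$trials, ground_truth = pop$ground_truth,
    metrics_plain = met_plain, metrics_cv = met_cv,
    mask = mask, overlap = overlap, curves = curves, deciles = deciles,
    mann_whitney = mw, matched = matched, sweep = sweep, seeds = seeds
  ))
}
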