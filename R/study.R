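# End-to-end study driver: sweep -> models -> metrics -> ranks/variances ->
# threshold analysis, with every table serialized to disk.

#' Configuration for a full study run
#'
#' @param data Input dataset tibble (binary `label` column plus features), or
#'   `NULL` to generate a synthetic dataset from `generator`.
#' @param generator A [generator_config()] used when `data` is `NULL`.
#' @param k,down_iters,up_iters,pool Sweep parameters, see [run_sweep()].
#' @param train_fraction Per-dataset train/test split fraction.
#' @param models Named list of model specs, see [default_model_specs()].
#' @param metrics Metric names, see [core_metrics()].
#' @param threshold Decision threshold for single-threshold metrics.
#' @param threshold_mode `"unique-scores"` or `"uniform-grid"` for the
#'   threshold analysis; see [threshold_sequence()].
#' @param sensitive Prevalence-sensitive metric group for the variance tests.
#' @param out_dir Output directory for the artifact bundle.
#' @param seed Global integer seed; all stage seeds derive from it.
#' @param write_threshold_grid Whether to serialize the full threshold grid
#'   (can be large); the aggregation curves and slopes are always written.
#' @return A `study_config` list.
#' @export
study_config <- function(data = NULL, generator = generator_config(),
                         k = 30, down_iters = 76, up_iters = 79,
                         pool = "original", train_fraction = 0.8,
                         models = default_model_specs(),
                         metrics = core_metrics(), threshold = 0.5,
                         threshold_mode = "unique-scores",
                         sensitive = sensitive_metrics(),
                         out_dir = "prevmetrics-study", seed = 1L,
                         write_threshold_grid = TRUE) {
  structure(
    list(data = data, generator = generator, k = k, down_iters = down_iters,
         up_iters = up_iters, pool = pool, train_fraction = train_fraction,
         models = models, metrics = metrics, threshold = threshold,
         threshold_mode = threshold_mode, sensitive = sensitive,
         out_dir = out_dir, seed = as.integer(seed),
         write_threshold_grid = isTRUE(write_threshold_grid)),
    class = "study_config"
  )
}

#' Read a study configuration from a YAML or JSON file
#'
#' Recognized top-level keys mirror the [study_config()] arguments (scalar
#' ones plus `generator: {n, target_prevalence, seed}` and
#' `models: [GLM, RF, ...]`); unknown keys are rejected.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A `study_config`.
#' @export
study_config_from_file <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML/JSON mapping")
  # YAML 1.1 reads a bare `n:` key as a boolean; restore the intended name
  fix_n_key <- function(x) {
    if (is.list(x)) {
      names(x)[names(x) %in% c("FALSE", "F")] <- "n"
      x <- lapply(x, fix_n_key)
    }
    x
  }
  raw <- fix_n_key(raw)
  known <- c("input_csv", "generator", "k", "down_iters", "up_iters", "pool",
             "train_fraction", "models", "metrics", "threshold",
             "threshold_mode", "out_dir", "seed", "write_threshold_grid")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- raw
  args$input_csv <- NULL
  if (!is.null(raw$input_csv)) {
    args$data <- read_labelled_csv(raw$input_csv)
  }
  if (!is.null(raw$generator)) {
    args$generator <- do.call(generator_config, raw$generator)
  }
  if (!is.null(raw$models)) {
    args$models <- default_model_specs(families = raw$models)
  }
  do.call(study_config, args)
}

#' Read a labelled input CSV
#'
#' Expects a header row and a binary `label` column; character columns are
#' read as factors.
#'
#' @param path CSV path.
#' @return A dataset tibble.
#' @export
read_labelled_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!"label" %in% names(d)) stop("input CSV must have a `label` column")
  d <- dplyr::mutate(d, dplyr::across(dplyr::where(is.character), factor))
  validate_dataset(d)
  d
}

#' Run the complete prevalence-consistency study
#'
#' Drives every stage end to end: obtains the input data (given or
#' synthetic), runs the constant-n prevalence sweep, fits all models on each
#' dataset, computes every metric, ranks models, computes value- and
#' rank-variances with the variance-homogeneity tests, runs the
#' all-thresholds analysis (grid, incremental averaging, OLS slopes) and the
#' correlation-drift check, and writes each table as CSV plus a JSON run
#' manifest and summary into `cfg$out_dir`.
#'
#' @param cfg A [study_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A `metric_study` object (list of all result tables plus the
#'   config), invisibly also written to disk.
#' @export
run_study <- function(cfg = study_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, code) {
    t <- Sys.time()
    out <- tryCatch(code, error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
    say("stage %-12s %6.1fs", name, as.numeric(Sys.time() - t, units = "secs"))
    out
  }

  data <- stage("input", {
    if (is.null(cfg$data)) generate_dataset(cfg$generator) else cfg$data
  })
  sweep <- stage("sweep", run_sweep(
    data, k = cfg$k, down_iters = cfg$down_iters, up_iters = cfg$up_iters,
    pool = cfg$pool, seed = derive_seed(cfg$seed, 1)
  ))
  drift <- stage("drift", correlation_drift(sweep))
  scores <- stage("models", score_sweep(
    sweep, cfg$models, cfg$train_fraction, seed = derive_seed(cfg$seed, 2)
  ))
  grid <- stage("metrics", evaluate_predictions(
    scores, cfg$metrics, threshold = cfg$threshold
  ))
  ranks <- stage("ranks", rank_models(grid))
  variances <- stage("variance", ranking_variance(grid, ranks))
  tests_value <- stage("tests", variance_equality_tests(grid, cfg$sensitive))
  tests_rank <- variance_equality_tests(ranks, cfg$sensitive)
  tgrid <- stage("thresholds", metric_threshold_grid(
    scores, cfg$metrics, mode = cfg$threshold_mode
  ))
  curves <- stage("aggregation", incremental_average(tgrid))
  slopes <- stage("slopes", ols_slope(curves))

  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    readr::write_csv(tibble::as_tibble(x), file.path(out_dir, name))
  }
  stage("write", {
    wr(dplyr::select(sweep, -"data"), "sweep_schedule.csv")
    wr(drift, "correlation_drift.csv")
    wr(grid, "metric_values.csv")
    wr(ranks, "model_ranks.csv")
    wr(variances, "variance_table.csv")
    wr(dplyr::bind_rows(
      dplyr::mutate(tests_value, on = "value", .before = 1),
      dplyr::mutate(tests_rank, on = "rank", .before = 1)
    ), "variance_tests.csv")
    if (cfg$write_threshold_grid) wr(tgrid, "threshold_grid.csv")
    wr(curves, "threshold_curves.csv")
    wr(slopes, "threshold_slopes.csv")
    manifest <- list(
      seed = cfg$seed,
      n = nrow(data),
      prevalence_full = mean(data$label),
      n_datasets = nrow(sweep),
      models = names(cfg$models),
      metrics = cfg$metrics,
      threshold = cfg$threshold,
      threshold_mode = cfg$threshold_mode,
      undefined_cells = sum(is.na(grid$value)),
      undefined_threshold_cells = sum(is.na(tgrid$value)),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("prevmetrics")),
      elapsed_s = as.numeric(Sys.time() - t0, units = "secs")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    mean_rank_var <- variances |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(mean_var_rank = mean(.data$var_rank), .groups = "drop") |>
      dplyr::arrange(.data$mean_var_rank)
    summary <- list(
      most_consistent_metric = mean_rank_var$metric[1],
      mean_rank_variance = as.list(setNames(mean_rank_var$mean_var_rank,
                                            mean_rank_var$metric)),
      variance_test_p_values = list(
        value = as.list(setNames(tests_value$p.value, tests_value$test)),
        rank = as.list(setNames(tests_rank$p.value, tests_rank$test))
      ),
      negative_significant_slopes = sum(
        slopes$slope < 0 & slopes$p.value < 0.05, na.rm = TRUE),
      slope_pairs = sum(!is.na(slopes$slope))
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  structure(
    list(config = cfg, sweep = sweep, drift = drift, predictions = scores,
         grid = grid, ranks = ranks, variances = variances,
         tests_value = tests_value, tests_rank = tests_rank,
         threshold_grid = tgrid, curves = curves, slopes = slopes,
         out_dir = out_dir),
    class = "metric_study"
  )
}

#' @export
print.metric_study <- function(x, ...) {
  cat("<metric_study>\n")
  cat("  datasets:", nrow(x$sweep),
      sprintf("(prevalence %.3f..%.3f)", min(x$sweep$prevalence),
              max(x$sweep$prevalence)), "\n")
  cat("  models:  ", paste(unique(x$grid$model), collapse = ", "), "\n")
  cat("  metrics: ", length(unique(x$grid$metric)), "\n")
  cat("  output:  ", x$out_dir, "\n")
  invisible(x)
}
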