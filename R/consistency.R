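# Evaluate every (dataset, model, metric) cell of a prevalence sweep, rank
# models per metric per dataset, and quantify consistency as variance across
# prevalence.

derive_seed <- function(seed, i, j = 0L) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 7919L * as.integer(i) + 104729L * as.integer(j)) %% 2147483647L
}

#' Fit and score every model on every dataset of a sweep
#'
#' For each dataset in the series: split into training and test parts, fit
#' each model spec (with cross-validated hyperparameters) on the training
#' part, and score the test part with positive-class probabilities. The
#' random-guess baseline uses the realized test-set prevalence.
#'
#' @param sweep A `sweep_series` from [run_sweep()] (any tibble with
#'   `iteration` and a `data` list-column works).
#' @param models Named list of model specs, see [default_model_specs()].
#' @param train_fraction Training fraction for the per-dataset split.
#' @param seed Integer seed; per-dataset sub-seeds are derived from it.
#' @return A tibble with one row per (dataset, model): `iteration`,
#'   `prevalence` (of the full dataset), `test_prevalence` (of the test
#'   split, the prevalence metric values refer to), `model`, and the scored
#'   predictions in the `preds` list-column.
#' @export
score_sweep <- function(sweep, models = default_model_specs(),
                        train_fraction = 0.8, seed = NULL) {
  stopifnot(all(c("iteration", "data") %in% names(sweep)))
  purrr::map_dfr(seq_len(nrow(sweep)), function(i) {
    parts <- split_train_test(sweep$data[[i]], train_fraction,
                              seed = derive_seed(seed, i))
    purrr::map_dfr(seq_along(models), function(j) {
      spec <- models[[j]]
      preds <- fit_predict(
        parts$train, parts$test, spec$family,
        grid = spec$grid, cv_folds = spec$cv_folds %||% 10,
        seed = derive_seed(seed, i, j)
      )
      tibble::tibble(
        iteration = sweep$iteration[i],
        prevalence = sweep$prevalence[i],
        test_prevalence = mean(parts$test$label),
        model = names(models)[j] %||% spec$family,
        preds = list(preds)
      )
    })
  })
}

#' Metric values for scored predictions
#'
#' Computes every requested metric for each (dataset, model) row of a scored
#' sweep: confusion-matrix metrics at the fixed decision threshold (default
#' 0.5) and AUC over all thresholds via [auc_rank()].
#'
#' @param scores Output of [score_sweep()].
#' @param metrics Character vector of metric names (default: the 18 core
#'   study metrics).
#' @param threshold Decision threshold for the confusion-matrix metrics.
#' @param rule Thresholding rule, see [confusion_at_threshold()].
#' @return An `evaluation_grid` tibble: `iteration`, `prevalence`,
#'   `test_prevalence`, `model`, `metric`, `value`, `undefined_reason`.
#' @export
evaluate_predictions <- function(scores, metrics = core_metrics(),
                                 threshold = 0.5, rule = "geq") {
  stopifnot(all(c("model", "preds") %in% names(scores)))
  cm_metrics <- setdiff(metrics, "AUC")
  out <- purrr::map_dfr(seq_len(nrow(scores)), function(i) {
    preds <- scores$preds[[i]]
    cm <- confusion_at_threshold(preds, threshold, rule = rule)
    vals <- metric_from_confusion(cm[c("tp", "fn", "tn", "fp")], cm_metrics)
    if ("AUC" %in% metrics) {
      vals <- dplyr::bind_rows(
        vals,
        tibble::tibble(metric = "AUC", value = auc_rank(preds),
                       undefined_reason = NA_character_)
      )
    }
    id <- scores[i, setdiff(names(scores), "preds"), drop = FALSE]
    dplyr::bind_cols(id[rep(1, nrow(vals)), , drop = FALSE], vals)
  })
  structure(out, class = c("evaluation_grid", class(out)))
}

#' Evaluate a full sweep in one call
#'
#' Convenience wrapper chaining [score_sweep()] and
#' [evaluate_predictions()]. The scored predictions are attached as the
#' `"predictions"` attribute (see [sweep_predictions()]) so the threshold
#' analysis can reuse them without refitting.
#'
#' @inheritParams score_sweep
#' @inheritParams evaluate_predictions
#' @return An `evaluation_grid` tibble, see [evaluate_predictions()].
#' @export
evaluate_grid <- function(sweep, models = default_model_specs(),
                          metrics = core_metrics(), train_fraction = 0.8,
                          threshold = 0.5, seed = NULL) {
  scores <- score_sweep(sweep, models, train_fraction, seed)
  grid <- evaluate_predictions(scores, metrics, threshold)
  attr(grid, "predictions") <- scores
  grid
}

#' @rdname evaluate_grid
#' @param grid An `evaluation_grid` produced by [evaluate_grid()].
#' @export
sweep_predictions <- function(grid) {
  attr(grid, "predictions")
}

#' Rank competing values with average tie-breaking
#'
#' Rank 1 is the best value under the metric's orientation; tied values share
#' the average of their positions. `NA` (undefined) values rank last, again
#' with ties averaged.
#'
#' @param x Numeric vector of metric values, one per model.
#' @param orientation `"higher"` if larger values are better, `"lower"`
#'   otherwise.
#' @return Numeric ranks summing to `m (m + 1) / 2`.
#' @examples
#' rank_values(c(0.689, 0.667, 0.657, 0.667, 0.687, 0.525))
#' @export
rank_values <- function(x, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  if (all(is.na(x))) stop("cannot rank: all values undefined")
  key <- if (orientation == "higher") -x else x
  r <- rank(key, ties.method = "average", na.last = "keep")
  nas <- is.na(x)
  if (any(nas)) {
    m <- length(x)
    r[nas] <- (m - sum(nas) + 1 + m) / 2
  }
  r
}

#' Rank models per dataset and metric
#'
#' @param grid An `evaluation_grid` tibble.
#' @return A `rank_table` tibble: `iteration`, `prevalence`, `metric`,
#'   `model`, `rank` (1 = best; ties averaged; undefined cells ranked last).
#' @export
rank_models <- function(grid) {
  stopifnot(all(c("iteration", "model", "metric", "value") %in% names(grid)))
  ori <- metric_orientation(unique(grid$metric))
  out <- grid |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("iteration", "prevalence", "test_prevalence", "metric")))) |>
    dplyr::mutate(rank = rank_values(
      .data$value, orientation = ori[[unique(.data$metric)]])) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::any_of(c("iteration", "prevalence", "metric",
                                  "model", "rank")))
  structure(out, class = c("rank_table", class(tibble::as_tibble(out))))
}

#' Variance of metric values and model ranks across prevalence
#'
#' For each (metric, model) pair: the sample variance, across the sweep's
#' datasets, of the raw metric value and of the model's rank under that
#' metric. This variance with respect to prevalence is the study's measure
#' of evaluation consistency. Undefined cells are excluded pairwise and
#' counted.
#'
#' @param grid An `evaluation_grid` tibble.
#' @param ranks Optionally a precomputed [rank_models()] table.
#' @return A `variance_table` tibble: `metric`, `model`, `var_value`,
#'   `var_rank`, `n_datasets`, `n_undefined`.
#' @export
ranking_variance <- function(grid, ranks = NULL) {
  if (is.null(ranks)) ranks <- rank_models(grid)
  if (length(unique(grid$iteration)) < 2) {
    stop("variance needs at least two datasets")
  }
  vv <- grid |>
    dplyr::group_by(.data$metric, .data$model) |>
    dplyr::summarise(
      var_value = var(.data$value, na.rm = TRUE),
      n_datasets = dplyr::n(),
      n_undefined = sum(is.na(.data$value)),
      .groups = "drop"
    )
  vr <- ranks |>
    dplyr::group_by(.data$metric, .data$model) |>
    dplyr::summarise(var_rank = var(.data$rank), .groups = "drop")
  out <- dplyr::left_join(vv, vr, by = c("metric", "model")) |>
    dplyr::select("metric", "model", "var_value", "var_rank",
                  "n_datasets", "n_undefined")
  structure(out, class = c("variance_table", class(tibble::as_tibble(out))))
}

#' Variance-homogeneity tests between metric groups
#'
#' Tests whether prevalence-sensitive metrics (by default the three
#' F-scores, Jaccard index, TNR, TPR and Fowlkes-Mallows) vary more across
#' the sweep than the remaining metrics. Cell values are first centered
#' within each (metric, model) pair so that dispersion measures variation
#' across prevalence, not differences in metric scale. The F-test compares
#' the two pooled groups; the Bartlett and Levene tests use the
#' metric-type-by-model interaction as the grouping factor.
#'
#' @param x An `evaluation_grid` (to test value variance) or a `rank_table`
#'   (to test ranking variance).
#' @param sensitive Character vector naming the prevalence-sensitive metric
#'   group; see [sensitive_metrics()].
#' @param value_col Column tested: `"value"` for grids, `"rank"` for rank
#'   tables (chosen automatically).
#' @return A `variance_test_results` tibble: `test`, `statistic`, `df1`,
#'   `df2`, `p.value`, `var_ratio` (pooled sensitive / insensitive variance),
#'   plus a `degenerate_groups` attribute counting zero-variance interaction
#'   cells.
#' @export
variance_equality_tests <- function(x, sensitive = sensitive_metrics(),
                                    value_col = NULL) {
  if (is.null(value_col)) {
    value_col <- if ("rank" %in% names(x)) "rank" else "value"
  }
  stopifnot(all(c("metric", "model", value_col) %in% names(x)))
  d <- tibble::tibble(metric = x$metric, model = x$model, y = x[[value_col]])
  d <- d[!is.na(d$y), , drop = FALSE]
  d$group <- ifelse(d$metric %in% sensitive, "sensitive", "insensitive")
  if (!any(d$group == "sensitive") || !any(d$group == "insensitive")) {
    stop("both metric groups must be non-empty")
  }
  d <- d |>
    dplyr::group_by(.data$metric, .data$model) |>
    dplyr::mutate(y = .data$y - mean(.data$y)) |>
    dplyr::ungroup()
  cell <- interaction(d$group, d$model, drop = TRUE)
  cell_var <- tapply(d$y, cell, var)
  degenerate <- sum(cell_var < .Machine$double.eps, na.rm = TRUE)
  if (degenerate > 0) {
    warning(degenerate, " zero-variance interaction group(s); ",
            "Bartlett/Levene statistics may be unstable")
  }
  ft <- stats::var.test(d$y[d$group == "sensitive"],
                        d$y[d$group == "insensitive"])
  bt <- stats::bartlett.test(d$y, cell)
  lt <- car::leveneTest(d$y, cell)
  out <- tibble::tibble(
    test = c("F", "Bartlett", "Levene"),
    statistic = c(unname(ft$statistic), unname(bt$statistic),
                  lt[1, "F value"]),
    df1 = c(unname(ft$parameter[1]), unname(bt$parameter), lt[1, "Df"]),
    df2 = c(unname(ft$parameter[2]), NA_real_, lt[2, "Df"]),
    p.value = c(ft$p.value, bt$p.value, lt[1, "Pr(>F)"]),
    var_ratio = unname(ft$estimate)
  )
  out <- structure(out, class = c("variance_test_results",
                                  class(tibble::as_tibble(out))))
  attr(out, "degenerate_groups") <- degenerate
  out
}
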