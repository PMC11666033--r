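# All-thresholds analysis: metric values over the full threshold grid,
# incremental threshold averaging, and variance-vs-threshold-count slopes.

#' Decision-threshold sequence ordered by distance from 0.5
#'
#' Returns the thresholds used for the incremental averaging analysis:
#' 0.5 first, then the remaining thresholds by increasing distance from 0.5,
#' ties broken toward the smaller threshold. Mode `"unique-scores"` uses the
#' distinct predicted scores of the test set (so the span of thresholds grows
#' outward from 0.5 until all attainable operating points are covered);
#' `"uniform-grid"` is an evenly spaced fallback for models that emit few
#' distinct scores.
#'
#' @param preds A scored-predictions tibble.
#' @param mode `"unique-scores"` (default) or `"uniform-grid"`.
#' @param n_grid Number of grid points for `"uniform-grid"`.
#' @return Numeric vector of thresholds, 0.5 first.
#' @examples
#' threshold_sequence(scored_predictions(c(1, 0, 1), c(0.2, 0.7, 0.7)))
#' @export
threshold_sequence <- function(preds, mode = c("unique-scores", "uniform-grid"),
                               n_grid = 101) {
  mode <- match.arg(mode)
  th <- if (mode == "unique-scores") {
    preds <- validate_scored(preds)
    if (nrow(preds) == 0) stop("empty predictions")
    unique(c(0.5, preds$score))
  } else {
    unique(c(0.5, seq(0, 1, length.out = n_grid)))
  }
  th[order(abs(th - 0.5), th)]
}

# Confusion counts at many thresholds in O((n + m) log n) via sorted scores.
threshold_counts <- function(preds, thresholds, rule = "geq") {
  pos_scores <- sort(preds$score[preds$label == 1])
  neg_scores <- sort(preds$score[preds$label == 0])
  n_pos <- length(pos_scores)
  n_neg <- length(neg_scores)
  count_called <- function(sorted, t) {
    # number of scores called positive at threshold t
    if (rule == "geq") {
      length(sorted) - findInterval(t, sorted, left.open = TRUE)
    } else {
      length(sorted) - findInterval(t, sorted)
    }
  }
  tp <- as.numeric(count_called(pos_scores, thresholds))
  fp <- as.numeric(count_called(neg_scores, thresholds))
  tibble::tibble(threshold = thresholds, tp = tp, fn = n_pos - tp,
                 tn = n_neg - fp, fp = fp)
}

#' Metric values over the full threshold grid
#'
#' For every (dataset, model) row of a scored sweep, computes each
#' confusion-matrix metric at every threshold of that row's
#' [threshold_sequence()]. AUC, which already integrates over all
#' thresholds, is constant across the grid by construction. Undefined cells
#' (e.g. PPV or DOR at extreme thresholds) are tagged, never dropped.
#'
#' @param scores Output of [score_sweep()].
#' @param metrics Metric names (default: the 18 core study metrics).
#' @param mode,n_grid Passed to [threshold_sequence()].
#' @param rule Thresholding rule, see [confusion_at_threshold()].
#' @return A `threshold_grid` tibble: `iteration`, `prevalence`, `model`,
#'   `threshold_index` (position in the distance-from-0.5 ordering, 1 being
#'   the 0.5 threshold), `threshold`, `metric`, `value`,
#'   `undefined_reason`.
#' @export
metric_threshold_grid <- function(scores, metrics = core_metrics(),
                                  mode = "unique-scores", n_grid = 101,
                                  rule = "geq") {
  stopifnot(all(c("model", "preds") %in% names(scores)))
  cm_metrics <- setdiff(metrics, "AUC")
  out <- purrr::map_dfr(seq_len(nrow(scores)), function(i) {
    preds <- scores$preds[[i]]
    th <- threshold_sequence(preds, mode = mode, n_grid = n_grid)
    cm <- threshold_counts(preds, th, rule = rule)
    cm$threshold_index <- seq_along(th)
    vals <- metric_from_confusion(cm, cm_metrics)
    if ("AUC" %in% metrics) {
      vals <- dplyr::bind_rows(vals, tibble::tibble(
        threshold = th, threshold_index = seq_along(th),
        metric = "AUC", value = auc_rank(preds),
        undefined_reason = NA_character_
      ))
    }
    id <- scores[i, intersect(names(scores),
                              c("iteration", "prevalence", "model")),
                 drop = FALSE]
    dplyr::bind_cols(id[rep(1, nrow(vals)), , drop = FALSE], vals)
  })
  structure(out, class = c("threshold_grid", class(out)))
}

#' Incremental threshold averaging
#'
#' Starting from the single threshold 0.5 and adding thresholds outward by
#' distance from 0.5, computes for each prefix the per-dataset mean metric
#' value over the included thresholds (undefined cells skipped), then the
#' variance of those means across the sweep's datasets. The number of
#' prefix sizes reported for a (metric, model) pair is the smallest
#' threshold count among its datasets, so every variance is computed over
#' the complete set of datasets.
#'
#' @param grid A `threshold_grid` from [metric_threshold_grid()].
#' @return An `aggregation_curve` tibble: `metric`, `model`,
#'   `n_thresholds`, `variance` (across datasets of the threshold-averaged
#'   value), `n_datasets`, `n_skipped` (datasets whose prefix was entirely
#'   undefined).
#' @export
incremental_average <- function(grid) {
  need <- c("iteration", "model", "threshold_index", "metric", "value")
  stopifnot(all(need %in% names(grid)))
  means <- grid |>
    dplyr::group_by(.data$metric, .data$model, .data$iteration) |>
    dplyr::arrange(.data$threshold_index, .by_group = TRUE) |>
    dplyr::mutate(
      .cum_n = cumsum(!is.na(.data$value)),
      .cum_mean = dplyr::if_else(
        .cum_n > 0,
        cumsum(dplyr::coalesce(.data$value, 0)) / .cum_n,
        NA_real_
      ),
      .prefix = dplyr::row_number()
    ) |>
    dplyr::ungroup()
  out <- means |>
    dplyr::group_by(.data$metric, .data$model) |>
    dplyr::mutate(.max_prefix = min(tapply(.data$.prefix, .data$iteration, max))) |>
    dplyr::filter(.data$.prefix <= .data$.max_prefix) |>
    dplyr::group_by(.data$metric, .data$model, n_thresholds = .data$.prefix) |>
    dplyr::summarise(
      variance = var(.data$.cum_mean, na.rm = TRUE),
      n_datasets = sum(!is.na(.data$.cum_mean)),
      n_skipped = sum(is.na(.data$.cum_mean)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$metric, .data$model, .data$n_thresholds)
  structure(out, class = c("aggregation_curve", class(tibble::as_tibble(out))))
}

#' Slope of metric variance in the number of thresholds
#'
#' Ordinary least squares of the across-dataset variance on the number of
#' thresholds included in the average, per (metric, model). A negative,
#' significant slope means that considering more decision thresholds makes
#' the metric's evaluation more consistent across prevalence.
#'
#' @param curve An `aggregation_curve` from [incremental_average()].
#' @return A `slope_table` tibble: `metric`, `model`, `slope`, `p.value`,
#'   `n_points`. Pairs with fewer than 3 curve points or a constant
#'   predictor are reported with `NA` slope.
#' @export
ols_slope <- function(curve) {
  stopifnot(all(c("metric", "model", "n_thresholds", "variance") %in%
                  names(curve)))
  fit_one <- function(d, ...) {
    ok <- !is.na(d$variance)
    if (sum(ok) < 3 || length(unique(d$n_thresholds[ok])) < 2) {
      return(tibble::tibble(slope = NA_real_, p.value = NA_real_,
                            n_points = sum(ok)))
    }
    if (sd(d$variance[ok]) == 0) {
      # exactly constant response (threshold-free metrics): flat by design
      return(tibble::tibble(slope = 0, p.value = 1, n_points = sum(ok)))
    }
    fit <- lm(variance ~ n_thresholds, data = d[ok, ])
    co <- suppressWarnings(summary(fit)$coefficients)
    slope <- unname(co[2, 1])
    p <- unname(co[2, 4])
    if (!is.finite(p)) {
      # exact fit (zero residual variance): flat curve is maximally
      # non-significant, a non-zero exact trend maximally significant
      p <- if (abs(slope) < 1e-14) 1 else 0
    }
    tibble::tibble(slope = slope, p.value = p, n_points = sum(ok))
  }
  out <- curve |>
    dplyr::group_by(.data$metric, .data$model) |>
    dplyr::group_modify(fit_one) |>
    dplyr::ungroup()
  structure(out, class = c("slope_table", class(tibble::as_tibble(out))))
}
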