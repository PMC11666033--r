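# broom-style tidiers for study objects.

#' Tidy a metric study
#'
#' @param x A `metric_study` from [run_study()].
#' @param ... Unused.
#' @return The evaluation grid: one row per (dataset, model, metric) with
#'   `value` and `undefined_reason`.
#' @export
tidy.metric_study <- function(x, ...) {
  tibble::as_tibble(x$grid)
}

#' Glance at a metric study
#'
#' @param x A `metric_study` from [run_study()].
#' @param ... Unused.
#' @return A one-row tibble summarising the run: dataset/model/metric counts,
#'   prevalence span, the metric with the smallest mean ranking variance,
#'   the number of undefined cells, and the share of negative significant
#'   variance-vs-thresholds slopes.
#' @export
glance.metric_study <- function(x, ...) {
  mean_rank_var <- x$variances |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(v = mean(.data$var_rank), .groups = "drop")
  tibble::tibble(
    n_datasets = nrow(x$sweep),
    n_models = length(unique(x$grid$model)),
    n_metrics = length(unique(x$grid$metric)),
    prevalence_min = min(x$sweep$prevalence),
    prevalence_max = max(x$sweep$prevalence),
    most_consistent_metric = mean_rank_var$metric[which.min(mean_rank_var$v)],
    n_undefined = sum(is.na(x$grid$value)),
    prop_negative_significant_slopes =
      mean(x$slopes$slope < 0 & x$slopes$p.value < 0.05, na.rm = TRUE)
  )
}

#' Glance at an evaluation grid
#'
#' @param x An `evaluation_grid` from [evaluate_grid()].
#' @param ... Unused.
#' @return A one-row tibble with the grid's dimensions and undefined-cell
#'   count.
#' @export
glance.evaluation_grid <- function(x, ...) {
  tibble::tibble(
    n_datasets = length(unique(x$iteration)),
    n_models = length(unique(x$model)),
    n_metrics = length(unique(x$metric)),
    n_undefined = sum(is.na(x$value))
  )
}
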