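# ggplot2 views of the study's result tables.

#' Plot metric values against prevalence
#'
#' One panel per metric, one line per model: the package's analogue of the
#' study's prevalence-response figures (points instead of LOESS smooths).
#'
#' @param object An `evaluation_grid`.
#' @param metrics Optional subset of metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_grid <- function(object, metrics = NULL, ...) {
  d <- tibble::as_tibble(object)
  if (!is.null(metrics)) d <- dplyr::filter(d, .data$metric %in% metrics)
  x_col <- if ("test_prevalence" %in% names(d)) "test_prevalence" else "prevalence"
  ggplot2::ggplot(d, ggplot2::aes(.data[[x_col]], .data$value,
                                  colour = .data$model)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "test-set prevalence", y = "metric value",
                  colour = "model")
}

#' Plot model ranks against prevalence
#'
#' @param object A `rank_table` from [rank_models()].
#' @param metrics Optional subset of metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rank_table <- function(object, metrics = NULL, ...) {
  d <- tibble::as_tibble(object)
  if (!is.null(metrics)) d <- dplyr::filter(d, .data$metric %in% metrics)
  ggplot2::ggplot(d, ggplot2::aes(.data$prevalence, .data$rank,
                                  colour = .data$model)) +
    ggplot2::geom_step(alpha = 0.8) +
    ggplot2::scale_y_reverse(breaks = function(l) seq_len(max(l))) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "prevalence", y = "rank (1 = best)", colour = "model")
}

#' Plot ranking variance per metric and model
#'
#' @param object A `variance_table` from [ranking_variance()].
#' @param what `"rank"` (default) or `"value"` variance.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.variance_table <- function(object, what = c("rank", "value"), ...) {
  what <- match.arg(what)
  col <- paste0("var_", what)
  d <- tibble::as_tibble(object)
  ord <- d |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(v = mean(.data[[col]]), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$v))
  d$metric <- factor(d$metric, levels = ord$metric)
  ggplot2::ggplot(d, ggplot2::aes(.data$metric, .data[[col]],
                                  fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste("variance of", what,
                                      "across prevalence"), fill = "model")
}

#' Plot variance against the number of thresholds averaged
#'
#' @param object An `aggregation_curve` from [incremental_average()].
#' @param metrics Optional subset of metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aggregation_curve <- function(object, metrics = NULL, ...) {
  d <- tibble::as_tibble(object)
  if (!is.null(metrics)) d <- dplyr::filter(d, .data$metric %in% metrics)
  ggplot2::ggplot(d, ggplot2::aes(.data$n_thresholds, .data$variance,
                                  colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of thresholds averaged",
                  y = "variance across datasets", colour = "model")
}

#' Plot the prevalence schedule of a sweep
#'
#' @param object A `sweep_series` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_series <- function(object, ...) {
  d <- dplyr::select(tibble::as_tibble(object), -"data")
  ggplot2::ggplot(d, ggplot2::aes(.data$iteration, .data$prevalence)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "sweep iteration (0 = original data)",
                  y = "prevalence")
}
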