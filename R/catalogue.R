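#' The metric catalogue
#'
#' All confusion-matrix metrics known to the package, plus the rank-based AUC,
#' as a machine-readable table. Each row gives the metric identifier, its
#' orientation (whether larger values indicate better models), its attainable
#' range, the F-score weight `beta` where applicable, and whether the metric
#' has a closed form in the `(n, phi, TPR, TNR)` parameterization.
#'
#' The `core` column flags the 18 metrics of the prevalence-consistency study:
#' TPR, TNR, PPV, NPV, accuracy, balanced accuracy (BA), bookmaker
#' informedness (BI, Youden's J), F1, the two weighted F-scores, MCC,
#' geometric mean, Fowlkes-Mallows index, markedness, diagnostic odds ratio,
#' Jaccard index, Cohen's kappa and AUC. The raw counts (TP, FN, TN, FP) and
#' the complement rates (FPR, FNR, FOR, FDR) are carried for ranking and
#' completeness; they are not part of the core set.
#'
#' @param beta Numeric vector of F-score weights to instantiate (in addition
#'   to F1). Defaults to the two commonly used values 0.5 and 2.
#' @return A tibble with columns `metric`, `label`, `orientation`
#'   (`"higher"` or `"lower"`), `lower`, `upper`, `beta`, `rates_form`,
#'   `threshold_free`, `core`.
#' @examples
#' metric_catalogue()
#' @export
metric_catalogue <- function(beta = c(0.5, 2)) {
  stopifnot(is.numeric(beta), all(beta > 0))
  base <- tibble::tribble(
    ~metric,    ~label,                    ~orientation, ~lower, ~upper, ~rates_form, ~core,
    "TP",       "True positives",          "higher",     0,      Inf,    TRUE,  FALSE,
    "FN",       "False negatives",         "lower",      0,      Inf,    TRUE,  FALSE,
    "TN",       "True negatives",          "higher",     0,      Inf,    TRUE,  FALSE,
    "FP",       "False positives",         "lower",      0,      Inf,    TRUE,  FALSE,
    "TPR",      "True positive rate",      "higher",     0,      1,      TRUE,  TRUE,
    "TNR",      "True negative rate",      "higher",     0,      1,      TRUE,  TRUE,
    "PPV",      "Positive predictive value", "higher",   0,      1,      TRUE,  TRUE,
    "NPV",      "Negative predictive value", "higher",   0,      1,      TRUE,  TRUE,
    "FPR",      "False positive rate",     "lower",      0,      1,      TRUE,  FALSE,
    "FNR",      "False negative rate",     "lower",      0,      1,      TRUE,  FALSE,
    "FOR",      "False omission rate",     "lower",      0,      1,      TRUE,  FALSE,
    "FDR",      "False discovery rate",    "lower",      0,      1,      TRUE,  FALSE,
    "accuracy", "Accuracy",                "higher",     0,      1,      TRUE,  TRUE,
    "BA",       "Balanced accuracy",       "higher",     0,      1,      TRUE,  TRUE,
    "BI",       "Bookmaker informedness",  "higher",    -1,      1,      TRUE,  TRUE,
    "MK",       "Markedness",              "higher",    -1,      1,      TRUE,  TRUE,
    "Gmean",    "Geometric mean",          "higher",     0,      1,      TRUE,  TRUE,
    "JI",       "Jaccard index",           "higher",     0,      1,      TRUE,  TRUE,
    "DOR",      "Diagnostic odds ratio",   "higher",     0,      Inf,    TRUE,  TRUE,
    "FM",       "Fowlkes-Mallows index",   "higher",     0,      1,      TRUE,  TRUE,
    "kappa",    "Cohen's kappa",           "higher",    -1,      1,      TRUE,  TRUE,
    "F1",       "F1 score",                "higher",     0,      1,      TRUE,  TRUE,
    "MCC",      "Matthews correlation coefficient", "higher", -1, 1,     TRUE,  TRUE,
    "AUC",      "Area under the ROC curve", "higher",    0,      1,      FALSE, TRUE
  )
  base$beta <- NA_real_
  beta_chr <- vapply(beta, function(b) format(b, trim = TRUE), character(1))
  fbeta <- tibble::tibble(
    metric = paste0("F", beta_chr),
    label = paste0("F-score (beta = ", beta_chr, ")"),
    orientation = "higher", lower = 0, upper = 1,
    rates_form = TRUE, core = TRUE, beta = as.numeric(beta)
  )
  out <- dplyr::bind_rows(base, fbeta)
  out$threshold_free <- out$metric == "AUC"
  dplyr::select(
    out, "metric", "label", "orientation", "lower", "upper", "beta",
    "rates_form", "threshold_free", "core"
  )
}

#' Names of the core study metrics
#'
#' @param beta F-score weights passed to [metric_catalogue()].
#' @return Character vector of the 18 core metric names.
#' @export
core_metrics <- function(beta = c(0.5, 2)) {
  cat <- metric_catalogue(beta)
  cat$metric[cat$core]
}

#' Prevalence-sensitive metric group
#'
#' The metrics with a close-to-monotone relationship with prevalence: the
#' three F-scores, the Jaccard index, TNR, TPR and the Fowlkes-Mallows index.
#' Used as one arm of the variance-homogeneity tests; the complement of this
#' set within the core metrics forms the insensitive group.
#'
#' @return Character vector of metric names.
#' @export
sensitive_metrics <- function() {
  c("F1", "F0.5", "F2", "JI", "TNR", "TPR", "FM")
}

metric_orientation <- function(metrics) {
  cat <- metric_catalogue()
  ori <- setNames(cat$orientation, cat$metric)
  extra <- setdiff(metrics, names(ori))
  if (length(extra)) {
    # user-instantiated F-scores are always higher-better
    ori[extra[grepl("^F[0-9.]+$", extra)]] <- "higher"
  }
  unknown <- setdiff(metrics, names(ori))
  if (length(unknown)) {
    stop("unknown metric(s): ", paste(unknown, collapse = ", "))
  }
  ori[metrics]
}
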