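# In-paper fixtures: the three worked MCC examples and the six published
# confusion matrices with their printed metric values. Used as exact oracles
# in tests and in the acceptance checks.

#' Published toy fixtures
#'
#' Returns the worked examples and published evaluation table that anchor the
#' metric algebra:
#'
#' * `worked_example_1..3` — three 10-observation label vectors with one, two
#'   and three misclassifications; their MCC values (0.82, 0.61, 0.36 at two
#'   decimals) and accuracies (0.9, 0.8, 0.7) illustrate how conservative MCC
#'   is relative to accuracy.
#' * `recidivism_<model>` — the published confusion-matrix counts of the six
#'   recidivism models on the 1243-row test set, with all printed metric
#'   values at three decimals.
#'
#' The `check` tag in the nested `expected` table says how each value can be
#' verified: `"exact"` values recompute from the counts; `"needs_scores"`
#' (AUC) cannot be recomputed from a single confusion matrix;
#' `"known_discrepant"` marks the two published weighted F-score rows, which
#' are inconsistent with the standard F-beta formula applied to the printed
#' counts (the formula behind those published numbers is not identifiable).
#'
#' @return A tibble with columns `name`, `truth` and `estimate` (label
#'   vectors, `NULL` for count-only fixtures), `tp`, `fn`, `tn`, `fp`, and a
#'   nested `expected` tibble (`metric`, `value`, `digits`, `check`).
#' @examples
#' fx <- toy_fixtures()
#' fx$expected[[1]]
#' @export
toy_fixtures <- function() {
  truth <- c(1, 0, 0, 0, 0, 1, 1, 0, 0, 1)
  worked <- list(
    worked_example_1 = list(
      estimate = c(1, 1, 0, 0, 0, 1, 1, 0, 0, 1),
      mcc = 0.82, accuracy = 0.9
    ),
    worked_example_2 = list(
      estimate = c(0, 0, 0, 0, 0, 1, 1, 0, 0, 0),
      mcc = 0.61, accuracy = 0.8
    ),
    worked_example_3 = list(
      estimate = c(0, 0, 1, 0, 0, 0, 1, 0, 0, 1),
      mcc = 0.36, accuracy = 0.7
    )
  )
  worked_rows <- purrr::imap_dfr(worked, function(w, nm) {
    cm <- confusion_from_labels(truth, w$estimate)
    tibble::tibble(
      name = nm, truth = list(truth), estimate = list(w$estimate),
      tp = cm$tp, fn = cm$fn, tn = cm$tn, fp = cm$fp,
      expected = list(tibble::tibble(
        metric = c("MCC", "accuracy"),
        value = c(w$mcc, w$accuracy),
        digits = 2, check = "exact"
      ))
    )
  })

  # published test-set evaluation of the six recidivism models
  metric_names <- c("TPR", "TNR", "PPV", "NPV", "accuracy", "BA", "BI",
                    "F1", "MCC", "Gmean", "FM", "MK", "DOR", "JI", "kappa",
                    "F0.5", "F2", "AUC")
  published <- list(
    GBM = list(cm = c(339, 223, 517, 164),
               v = c(0.603, 0.759, 0.674, 0.699, 0.689, 0.681, 0.362,
                     0.637, 0.367, 0.677, 0.638, 0.373, 4.792, 0.467, 0.366,
                     0.352, 0.512, 0.734)),
    GLM = list(cm = c(292, 270, 537, 144),
               v = c(0.520, 0.789, 0.670, 0.665, 0.667, 0.654, 0.308,
                     0.585, 0.321, 0.640, 0.590, 0.335, 4.033, 0.414, 0.314,
                     0.321, 0.450, 0.718)),
    KNN = list(cm = c(296, 266, 521, 160),
               v = c(0.527, 0.765, 0.649, 0.662, 0.657, 0.646, 0.292,
                     0.582, 0.301, 0.635, 0.585, 0.311, 3.623, 0.410, 0.297,
                     0.319, 0.453, 0.694)),
    LDA = list(cm = c(286, 276, 543, 138),
               v = c(0.509, 0.797, 0.675, 0.663, 0.667, 0.653, 0.306,
                     0.580, 0.322, 0.637, 0.586, 0.338, 4.077, 0.409, 0.313,
                     0.317, 0.442, 0.717)),
    RF = list(cm = c(311, 251, 543, 138),
              v = c(0.553, 0.797, 0.693, 0.684, 0.687, 0.675, 0.351,
                    0.615, 0.363, 0.664, 0.619, 0.377, 4.875, 0.444, 0.357,
                    0.338, 0.477, 0.727)),
    random_guess = list(cm = c(267, 295, 386, 295),
                        v = c(0.475, 0.567, 0.475, 0.567, 0.525, 0.521, 0.042,
                              0.475, 0.042, 0.519, 0.475, 0.042, 1.184, 0.312,
                              0.042, 0.264, 0.396, 0.524))
  )
  table_rows <- purrr::imap_dfr(published, function(p, nm) {
    check <- rep("exact", length(metric_names))
    check[metric_names == "AUC"] <- "needs_scores"
    check[metric_names %in% c("F0.5", "F2")] <- "known_discrepant"
    tibble::tibble(
      name = paste0("recidivism_", nm), truth = list(NULL),
      estimate = list(NULL),
      tp = p$cm[1], fn = p$cm[2], tn = p$cm[3], fp = p$cm[4],
      expected = list(tibble::tibble(
        metric = metric_names, value = p$v, digits = 3, check = check
      ))
    )
  })
  dplyr::bind_rows(worked_rows, table_rows)
}

#' Round half up to a number of decimal places
#'
#' Rounding convention used when comparing computed values against published
#' ones (R's `round()` rounds half to even). Applied only in comparisons,
#' never inside computations.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
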