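#' Build confusion matrices as tibble rows
#'
#' A confusion matrix is stored as one tibble row with the four counts
#' `tp`, `fn`, `tn`, `fp` (true/false positives/negatives at one decision
#' threshold). All downstream metric functions are vectorized over rows, so a
#' tibble of confusion matrices — one per threshold, per dataset, per model —
#' is the package's working object.
#'
#' @param tp,fn,tn,fp Non-negative integer counts, recycled to a common
#'   length; each row must have a positive total.
#' @return A tibble with columns `tp`, `fn`, `tn`, `fp`.
#' @examples
#' confusion_matrix(tp = 339, fn = 223, tn = 517, fp = 164)
#' @export
confusion_matrix <- function(tp, fn, tn, fp) {
  cm <- tibble::tibble(tp = as.numeric(tp), fn = as.numeric(fn),
                       tn = as.numeric(tn), fp = as.numeric(fp))
  validate_confusion(cm)
  cm
}

validate_confusion <- function(cm) {
  need <- c("tp", "fn", "tn", "fp")
  if (!all(need %in% names(cm))) {
    stop("confusion matrix needs columns tp, fn, tn, fp")
  }
  counts <- as.matrix(cm[need])
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("confusion counts must be finite and non-negative")
  }
  if (any(rowSums(counts) <= 0)) stop("confusion matrix total must be positive")
  invisible(cm)
}

check_binary <- function(x, what) {
  if (!all(x %in% c(0, 1))) stop(what, " must contain only 0 and 1")
  as.numeric(x)
}

#' Confusion matrix from true and predicted labels
#'
#' @param truth Binary vector (0/1) of true class labels.
#' @param estimate Binary vector (0/1) of predicted class labels, same length.
#' @return A one-row confusion tibble (see [confusion_matrix()]).
#' @examples
#' confusion_from_labels(c(1, 0, 0, 0, 0, 1, 1, 0, 0, 1),
#'                       c(1, 1, 0, 0, 0, 1, 1, 0, 0, 1))
#' @export
confusion_from_labels <- function(truth, estimate) {
  if (length(truth) != length(estimate)) stop("truth and estimate lengths differ")
  if (length(truth) < 1) stop("empty label vectors")
  truth <- check_binary(truth, "truth")
  estimate <- check_binary(estimate, "estimate")
  confusion_matrix(
    tp = sum(truth == 1 & estimate == 1),
    fn = sum(truth == 1 & estimate == 0),
    tn = sum(truth == 0 & estimate == 0),
    fp = sum(truth == 0 & estimate == 1)
  )
}

#' Scored predictions for one test set
#'
#' @param label Binary vector (0/1) of true labels.
#' @param score Predicted positive-class probabilities in `[0, 1]`.
#' @return A tibble with columns `label` and `score`.
#' @export
scored_predictions <- function(label, score) {
  if (length(label) != length(score)) stop("label and score lengths differ")
  label <- check_binary(label, "label")
  score <- as.numeric(score)
  if (any(!is.finite(score)) || any(score < 0 | score > 1)) {
    stop("scores must lie in [0, 1]")
  }
  tibble::tibble(label = label, score = score)
}

#' Read scored predictions from a CSV file
#'
#' Expects a header row with columns `label` (0/1) and `score` (probability
#' in `[0, 1]`); extra columns are ignored.
#'
#' @param path CSV path.
#' @return A scored-predictions tibble.
#' @export
read_scored_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("label", "score") %in% names(d))) {
    stop("scored-prediction CSV needs columns label and score")
  }
  scored_predictions(d$label, d$score)
}

validate_scored <- function(preds) {
  if (!all(c("label", "score") %in% names(preds))) {
    stop("scored predictions need columns label and score")
  }
  scored_predictions(preds$label, preds$score)
}

#' Confusion matrix at one or more decision thresholds
#'
#' Converts scored predictions to hard labels at each threshold and counts the
#' four cells. By default a case is called positive when its score is greater
#' than or equal to the threshold, so `t = 0` predicts every case positive and
#' a score exactly at the cutoff is called positive.
#'
#' @param preds A scored-predictions tibble (columns `label`, `score`).
#' @param threshold Numeric vector of thresholds in `[0, 1]`.
#' @param rule `"geq"` (default) calls `score >= t` positive; `"gt"` uses a
#'   strict inequality.
#' @return A tibble with one row per threshold: `threshold`, `tp`, `fn`,
#'   `tn`, `fp`.
#' @examples
#' preds <- scored_predictions(c(1, 0), c(0.9, 0.1))
#' confusion_at_threshold(preds, 0.5)
#' @export
confusion_at_threshold <- function(preds, threshold, rule = c("geq", "gt")) {
  preds <- validate_scored(preds)
  rule <- match.arg(rule)
  stopifnot(is.numeric(threshold), all(threshold >= 0 & threshold <= 1))
  pos <- preds$label == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  cells <- vapply(threshold, function(t) {
    called <- if (rule == "geq") preds$score >= t else preds$score > t
    tp <- sum(called & pos)
    fp <- sum(called & !pos)
    c(tp = tp, fn = n_pos - tp, tn = n_neg - fp, fp = fp)
  }, numeric(4))
  out <- tibble::as_tibble(t(cells))
  dplyr::bind_cols(tibble::tibble(threshold = threshold), out)
}

#' Convert between count and rate parameterizations
#'
#' Every confusion matrix is equivalently described by the quadruple
#' `(n, phi, tpr, tnr)`: sample size, prevalence of the positive class, true
#' positive rate and true negative rate. `as_rates()` maps counts to rates;
#' `as_counts()` maps back (exactly when the implied counts are integral).
#'
#' @param cm A confusion tibble with columns `tp`, `fn`, `tn`, `fp`.
#' @return `as_rates()`: a tibble with columns `n`, `phi`, `tpr`, `tnr`
#'   (rates are `NA` for an absent class). Extra columns are carried through.
#' @examples
#' as_rates(confusion_matrix(339, 223, 517, 164))
#' @export
as_rates <- function(cm) {
  validate_confusion(cm)
  n <- cm$tp + cm$fn + cm$tn + cm$fp
  pos <- cm$tp + cm$fn
  neg <- cm$tn + cm$fp
  out <- tibble::tibble(
    n = n,
    phi = pos / n,
    tpr = ifelse(pos > 0, cm$tp / pos, NA_real_),
    tnr = ifelse(neg > 0, cm$tn / neg, NA_real_)
  )
  extra <- setdiff(names(cm), c("tp", "fn", "tn", "fp"))
  if (length(extra)) out <- dplyr::bind_cols(cm[extra], out)
  out
}

#' @param rates A tibble with columns `n`, `phi`, `tpr`, `tnr`.
#' @rdname as_rates
#' @export
as_counts <- function(rates) {
  validate_rates(rates)
  pos <- rates$phi * rates$n
  neg <- (1 - rates$phi) * rates$n
  out <- tibble::tibble(
    tp = rates$tpr * pos, fn = (1 - rates$tpr) * pos,
    tn = rates$tnr * neg, fp = (1 - rates$tnr) * neg
  )
  extra <- setdiff(names(rates), c("n", "phi", "tpr", "tnr"))
  if (length(extra)) out <- dplyr::bind_cols(rates[extra], out)
  out
}

validate_rates <- function(rates) {
  need <- c("n", "phi", "tpr", "tnr")
  if (!all(need %in% names(rates))) {
    stop("rates need columns n, phi, tpr, tnr")
  }
  with(rates, {
    if (any(n <= 0)) stop("n must be positive")
    if (any(phi < 0 | phi > 1, na.rm = TRUE)) stop("phi must lie in [0, 1]")
    if (any(tpr < 0 | tpr > 1, na.rm = TRUE)) stop("tpr must lie in [0, 1]")
    if (any(tnr < 0 | tnr > 1, na.rm = TRUE)) stop("tnr must lie in [0, 1]")
  })
  invisible(rates)
}
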