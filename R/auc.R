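#' Rank-based AUC (normalized Mann-Whitney U)
#'
#' The area under the ROC curve computed as the probability that a randomly
#' chosen positive case is scored above a randomly chosen negative case, with
#' score ties credited one half. Computed from average ranks, it equals the
#' normalized Wilcoxon/Mann-Whitney statistic and is invariant under any
#' strictly increasing transformation of the scores.
#'
#' @param preds A scored-predictions tibble (columns `label`, `score`).
#' @return A single number in `[0, 1]`.
#' @examples
#' auc_rank(scored_predictions(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)))
#' @export
auc_rank <- function(preds) {
  preds <- validate_scored(preds)
  pos <- preds$label == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC needs at least one case of each class")
  }
  r <- rank(preds$score)   # average ranks credit ties with 0.5
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' One `(FPR, TPR)` point per distinct score under the `score >= t` decision
#' rule, preceded by the `(0, 0)` anchor (threshold above every score). The
#' final point is always `(1, 1)`, reached when the threshold equals the
#' smallest score. The trapezoidal area under these points equals
#' [auc_rank()].
#'
#' @inheritParams auc_rank
#' @return A tibble with columns `threshold` (`Inf` for the anchor), `fpr`,
#'   `tpr`, both monotone non-decreasing.
#' @export
roc_points <- function(preds) {
  preds <- validate_scored(preds)
  pos <- preds$label == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs at least one case of each class")
  }
  cuts <- sort(unique(preds$score), decreasing = TRUE)
  tp <- vapply(cuts, function(t) sum(pos & preds$score >= t), numeric(1))
  fp <- vapply(cuts, function(t) sum(!pos & preds$score >= t), numeric(1))
  tibble::tibble(
    threshold = c(Inf, cuts),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
}

#' Trapezoidal area under ROC points
#'
#' @param roc A tibble as returned by [roc_points()].
#' @return Area under the curve.
#' @export
roc_auc_trapezoid <- function(roc) {
  stopifnot(all(c("fpr", "tpr") %in% names(roc)))
  dx <- diff(roc$fpr)
  sum(dx * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}
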