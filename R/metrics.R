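# Metric kernels. Each kernel returns list(value, reason): value is NA exactly
# when a formula denominator is zero, and reason carries the zero-denominator
# tag. All kernels are vectorized over confusion-matrix rows.

tagged <- function(value, undefined, reason) {
  value[undefined] <- NA_real_
  list(value = value,
       reason = ifelse(undefined, reason, NA_character_))
}

safe_div <- function(num, den, reason) {
  tagged(ifelse(den == 0, NA_real_, num / den), den == 0, reason)
}

fbeta_from_name <- function(metric) {
  as.numeric(sub("^F", "", metric))
}

metric_kernel_counts <- function(metric, tp, fn, tn, fp, beta = NA_real_) {
  n <- tp + fn + tn + fp
  switch(metric,
    TP = tagged(tp, rep(FALSE, length(tp)), ""),
    FN = tagged(fn, rep(FALSE, length(tp)), ""),
    TN = tagged(tn, rep(FALSE, length(tp)), ""),
    FP = tagged(fp, rep(FALSE, length(tp)), ""),
    TPR = safe_div(tp, tp + fn, "TP+FN=0"),
    TNR = safe_div(tn, tn + fp, "TN+FP=0"),
    PPV = safe_div(tp, tp + fp, "TP+FP=0"),
    NPV = safe_div(tn, tn + fn, "TN+FN=0"),
    FPR = safe_div(fp, tn + fp, "TN+FP=0"),
    FNR = safe_div(fn, tp + fn, "TP+FN=0"),
    FOR = safe_div(fn, tn + fn, "TN+FN=0"),
    FDR = safe_div(fp, tp + fp, "TP+FP=0"),
    accuracy = safe_div(tp + tn, n, "n=0"),
    BA = {
      und <- (tp + fn) == 0 | (tn + fp) == 0
      tagged((tp / (tp + fn) + tn / (tn + fp)) / 2, und, "one class absent")
    },
    BI = {
      und <- (tp + fn) == 0 | (tn + fp) == 0
      tagged(tp / (tp + fn) + tn / (tn + fp) - 1, und, "one class absent")
    },
    MK = {
      und <- (tp + fp) == 0 | (tn + fn) == 0
      tagged(tp / (tp + fp) + tn / (tn + fn) - 1, und,
             "TP+FP=0 or TN+FN=0")
    },
    Gmean = {
      und <- (tp + fn) == 0 | (tn + fp) == 0
      tagged(sqrt((tp / (tp + fn)) * (tn / (tn + fp))), und,
             "one class absent")
    },
    JI = safe_div(tp, tp + fn + fp, "TP+FN+FP=0"),
    DOR = {
      und <- (tp + fn) == 0 | (tn + fp) == 0
      fpr <- fp / (tn + fp)
      fnr <- fn / (tp + fn)
      und <- und | (fpr * fnr) == 0
      tagged(((tp / (tp + fn)) * (tn / (tn + fp))) / (fpr * fnr), und,
             "FPR*FNR=0")
    },
    FM = {
      und <- (tp + fn) == 0 | (tp + fp) == 0
      tagged(sqrt((tp / (tp + fp)) * (tp / (tp + fn))), und,
             "TP+FP=0 or TP+FN=0")
    },
    kappa = {
      exp_acc <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
      und <- exp_acc == 1
      tagged(((tp + tn) / n - exp_acc) / (1 - exp_acc), und, "expAccuracy=1")
    },
    F1 = safe_div(2 * tp, 2 * tp + fp + fn, "2TP+FP+FN=0"),
    MCC = {
      den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      tagged((tp * tn - fp * fn) / sqrt(den2), den2 == 0,
             "zero confusion marginal")
    },
    AUC = stop("AUC is rank-based and cannot be computed from one confusion matrix; use auc_rank()"),
    {
      if (grepl("^F[0-9.]+$", metric)) {
        b <- if (is.na(beta)) fbeta_from_name(metric) else beta
        und <- (tp + fn) == 0 | (tp + fp) == 0
        ppv <- tp / (tp + fp)
        tprv <- tp / (tp + fn)
        den <- b^2 * ppv + tprv
        und <- und | den == 0
        tagged((1 + b^2) * ppv * tprv / den, und,
               "beta^2*PPV+TPR=0 or PPV/TPR undefined")
      } else stop("unknown metric: ", metric)
    }
  )
}

metric_kernel_rates <- function(metric, n, phi, tpr, tnr, beta = NA_real_) {
  # An NA rate is legitimate when its class is absent (phi 0 or 1): the rate
  # then only ever enters multiplied by a zero class weight, so it is zeroed
  # out. An NA rate for a class that is present leaves the metric undefined.
  na_tpr <- is.na(tpr)
  na_tnr <- is.na(tnr)
  und_pos <- phi > 0 & na_tpr
  und_neg <- phi < 1 & na_tnr
  no_pos <- phi == 0 | na_tpr   # TPR side unusable
  no_neg <- phi == 1 | na_tnr
  tpr <- ifelse(na_tpr, 0, tpr)
  tnr <- ifelse(na_tnr, 0, tnr)
  fpr <- 1 - tnr
  fnr <- 1 - tpr
  # per-class contributions with exact-zero weights at the boundary
  w_pos <- function(x) ifelse(phi == 0, 0, x * phi)
  w_neg <- function(x) ifelse(phi == 1, 0, x * (1 - phi))
  both <- und_pos | und_neg
  und_tag <- function(value, und, reason) tagged(value, und | both, reason)
  switch(metric,
    TP = und_tag(w_pos(tpr) * n, FALSE, ""),
    FN = und_tag(w_pos(fnr) * n, FALSE, ""),
    TN = und_tag(w_neg(tnr) * n, FALSE, ""),
    FP = und_tag(w_neg(fpr) * n, FALSE, ""),
    TPR = tagged(tpr, no_pos, "TP+FN=0"),
    TNR = tagged(tnr, no_neg, "TN+FP=0"),
    FPR = tagged(fpr, no_neg, "TN+FP=0"),
    FNR = tagged(fnr, no_pos, "TP+FN=0"),
    accuracy = und_tag(w_pos(tpr) + w_neg(tnr), FALSE, "one class absent"),
    PPV = und_tag(w_pos(tpr) / (w_pos(tpr) + w_neg(fpr)),
                  (w_pos(tpr) + w_neg(fpr)) == 0, "TP+FP=0"),
    NPV = und_tag(w_neg(tnr) / (w_neg(tnr) + w_pos(fnr)),
                  (w_neg(tnr) + w_pos(fnr)) == 0, "TN+FN=0"),
    FDR = und_tag(w_neg(fpr) / (w_pos(tpr) + w_neg(fpr)),
                  (w_pos(tpr) + w_neg(fpr)) == 0, "TP+FP=0"),
    FOR = und_tag(w_pos(fnr) / (w_neg(tnr) + w_pos(fnr)),
                  (w_neg(tnr) + w_pos(fnr)) == 0, "TN+FN=0"),
    BA = und_tag((tpr + tnr) / 2, no_pos | no_neg, "one class absent"),
    BI = und_tag(tpr + tnr - 1, no_pos | no_neg, "one class absent"),
    MK = {
      den_p <- w_pos(tpr) + w_neg(fpr)
      den_n <- w_neg(tnr) + w_pos(fnr)
      und_tag(w_pos(tpr) / den_p + w_neg(tnr) / den_n - 1,
              den_p == 0 | den_n == 0, "TP+FP=0 or TN+FN=0")
    },
    Gmean = und_tag(sqrt(tpr * tnr), no_pos | no_neg, "one class absent"),
    JI = {
      den <- phi + w_neg(fpr)
      und_tag(w_pos(tpr) / den, den == 0, "TP+FN+FP=0")
    },
    DOR = und_tag(tpr * tnr / (fpr * fnr),
                  no_pos | no_neg | (fpr * fnr) == 0, "FPR*FNR=0"),
    FM = {
      den <- w_pos(tpr) + w_neg(fpr)
      und_tag(sqrt(tpr^2 * phi / den), no_pos | den == 0,
              "TP+FP=0 or TP+FN=0")
    },
    kappa = {
      # expAccuracy in its n^2-normalized form, a function of (phi, tpr, tnr)
      exp_acc <- phi^2 * tpr + phi * (1 - phi) * (2 - tpr - tnr) +
        (1 - phi)^2 * tnr
      acc <- w_pos(tpr) + w_neg(tnr)
      und_tag((acc - exp_acc) / (1 - exp_acc), exp_acc == 1, "expAccuracy=1")
    },
    F1 = {
      den <- 2 * w_pos(tpr) + w_neg(fpr) + w_pos(fnr)
      und_tag(2 * w_pos(tpr) / den, den == 0, "2TP+FP+FN=0")
    },
    MCC = {
      a <- ifelse(phi == 1, NA_real_, w_pos(tpr) / (1 - phi) + fpr)
      b <- ifelse(phi == 0, NA_real_, w_neg(tnr) / phi + fnr)
      und_tag((tpr + tnr - 1) / sqrt(a * b),
              no_pos | no_neg | is.na(a) | is.na(b) | a == 0 | b == 0,
              "zero confusion marginal")
    },
    AUC = stop("AUC has no (n, phi, TPR, TNR) form; use auc_rank()"),
    {
      if (grepl("^F[0-9.]+$", metric)) {
        b <- if (is.na(beta)) fbeta_from_name(metric) else beta
        den_p <- w_pos(tpr) + w_neg(fpr)
        ppv <- w_pos(tpr) / den_p
        den <- b^2 * ppv + tpr
        und <- no_pos | den_p == 0 | den == 0
        ppv[is.na(ppv)] <- 0
        und_tag((1 + b^2) * ppv * tpr / ifelse(den == 0, 1, den), und,
                "beta^2*PPV+TPR=0 or PPV/TPR undefined")
      } else stop("unknown metric: ", metric)
    }
  )
}

metric_table <- function(x, metrics, kernel) {
  purrr::map_dfr(metrics, function(m) {
    k <- kernel(m, x)
    tibble::tibble(metric = m, value = k$value,
                   undefined_reason = k$reason, .row = seq_along(k$value))
  })
}

#' Evaluate metrics on confusion matrices
#'
#' Computes the requested catalogue metrics from the four counts. A metric
#' whose formula has an exactly zero denominator returns `NA` with the
#' zero-denominator tag in `undefined_reason` (never `Inf` or `NaN`), so
#' downstream aggregation can skip and count such cells.
#'
#' @param cm A confusion tibble (columns `tp`, `fn`, `tn`, `fp`; extra
#'   columns such as `threshold` are carried through to the output).
#' @param metrics Character vector of catalogue metric names. Defaults to all
#'   core study metrics computable from a single confusion matrix (i.e.
#'   excluding AUC, which needs scores; see [auc_rank()]).
#' @return A long tibble: the carried-through identifier columns plus
#'   `metric`, `value`, `undefined_reason`.
#' @examples
#' cm <- confusion_matrix(339, 223, 517, 164)
#' metric_from_confusion(cm, c("MCC", "kappa", "DOR"))
#' @export
metric_from_confusion <- function(cm, metrics = NULL) {
  validate_confusion(cm)
  if (is.null(metrics)) metrics <- setdiff(core_metrics(), "AUC")
  out <- metric_table(cm, metrics, function(m, x) {
    metric_kernel_counts(m, x$tp, x$fn, x$tn, x$fp)
  })
  bind_carry(cm, c("tp", "fn", "tn", "fp"), out)
}

#' Evaluate metrics from the (n, phi, TPR, TNR) parameterization
#'
#' Computes metrics from sample size, prevalence, true positive rate and true
#' negative rate using the closed forms in those four quantities, e.g.
#' `accuracy = TPR * phi + TNR * (1 - phi)`. For Cohen's kappa the expected
#' accuracy is the n-squared-normalized form
#' `phi^2 TPR + phi (1 - phi) (2 - TPR - TNR) + (1 - phi)^2 TNR`.
#' Values agree with [metric_from_confusion()] on the equivalent counts to
#' floating-point accuracy.
#'
#' @param rates A tibble with columns `n`, `phi`, `tpr`, `tnr` (extra columns
#'   carried through).
#' @param metrics Character vector of metric names; AUC is rejected since it
#'   has no single-threshold form.
#' @return A long tibble as in [metric_from_confusion()].
#' @examples
#' metric_from_rates(tibble::tibble(n = 1243, phi = 562 / 1243,
#'                                  tpr = 339 / 562, tnr = 517 / 681),
#'                   c("accuracy", "MCC", "F1"))
#' @export
metric_from_rates <- function(rates, metrics = NULL) {
  validate_rates(rates)
  if (is.null(metrics)) metrics <- setdiff(core_metrics(), "AUC")
  if ("AUC" %in% metrics) stop("AUC has no (n, phi, TPR, TNR) form; use auc_rank()")
  out <- metric_table(rates, metrics, function(m, x) {
    metric_kernel_rates(m, x$n, x$phi, x$tpr, x$tnr)
  })
  bind_carry(rates, c("n", "phi", "tpr", "tnr"), out)
}

bind_carry <- function(x, drop_cols, long) {
  extra <- setdiff(names(x), drop_cols)
  if (length(extra)) {
    carried <- x[long$.row, extra, drop = FALSE]
    long <- dplyr::bind_cols(tibble::as_tibble(carried), long)
  }
  long$.row <- NULL
  long
}
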