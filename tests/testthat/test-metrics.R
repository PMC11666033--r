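test_that("published fixture values recompute from their counts", {
  fx <- toy_fixtures()
  for (i in seq_len(nrow(fx))) {
    exp <- dplyr::filter(fx$expected[[i]], .data$check == "exact")
    got <- metric_from_confusion(fx[i, c("tp", "fn", "tn", "fp")],
                                 exp$metric)
    expect_equal(round_half_up(got$value, exp$digits), exp$value,
                 info = fx$name[i])
  }
})

test_that("label vectors of count-only fixtures regenerate their counts", {
  fx <- dplyr::filter(toy_fixtures(), !purrr::map_lgl(truth, is.null))
  expect_gt(nrow(fx), 0)
  for (i in seq_len(nrow(fx))) {
    cm <- confusion_from_labels(fx$truth[[i]], fx$estimate[[i]])
    expect_equal(unlist(cm), unlist(fx[i, c("tp", "fn", "tn", "fp")]))
  }
})

test_that("published weighted F-scores are flagged as non-reproducible", {
  # the standard F-beta formula on the published counts gives materially
  # different numbers than the published rows, which toy_fixtures() tags
  fx <- toy_fixtures()
  gbm <- fx[fx$name == "recidivism_GBM", ]
  exp <- gbm$expected[[1]]
  flagged <- dplyr::filter(exp, .data$check == "known_discrepant")
  expect_setequal(flagged$metric, c("F0.5", "F2"))
  got <- metric_from_confusion(gbm[, c("tp", "fn", "tn", "fp")],
                               c("F0.5", "F2"))
  expect_equal(round_half_up(got$value, 3), c(0.659, 0.616))
  expect_true(all(abs(got$value - flagged$value) > 0.05))
})

test_that("zero denominators yield tagged undefined values, never NaN/Inf", {
  cm <- confusion_matrix(0, 5, 5, 0)
  out <- metric_from_confusion(cm, c("PPV", "FDR", "MCC", "DOR", "FM"))
  expect_true(all(is.na(out$value)))
  expect_true(all(!is.na(out$undefined_reason)))
  expect_match(out$undefined_reason[out$metric == "PPV"], "TP\\+FP=0")
  # defined metrics on the same matrix stay finite
  ok <- metric_from_confusion(cm, c("accuracy", "TPR", "TNR", "F1", "JI"))
  expect_true(all(is.finite(ok$value)))
  expect_equal(ok$value[ok$metric == "F1"], 0)
  expect_error(metric_from_confusion(cm, "notametric"), "unknown metric")
  expect_error(metric_from_confusion(cm, "AUC"), "auc_rank")
})

test_that("count and rate forms agree on random confusion matrices", {
  set.seed(421)
  cm <- random_confusions(500, min_count = 0)
  mets <- setdiff(core_metrics(), "AUC")
  a <- metric_from_confusion(cm, mets)
  b <- metric_from_rates(as_rates(cm), mets)
  expect_equal(is.na(a$value), is.na(b$value))
  expect_lt(max(abs(a$value - b$value), na.rm = TRUE), 1e-10)
  expect_error(metric_from_rates(as_rates(cm), "AUC"), "auc_rank")
})

test_that("metric values respect their catalogued ranges", {
  set.seed(99)
  cm <- random_confusions(400)
  cat <- metric_catalogue()
  vals <- metric_from_confusion(cm, setdiff(cat$metric, "AUC"))
  joined <- dplyr::left_join(vals, cat, by = "metric")
  ok <- is.na(joined$value) |
    (joined$value >= joined$lower - 1e-12 &
       joined$value <= joined$upper + 1e-12)
  expect_true(all(ok))
})

test_that("MCC equals the Pearson correlation of the label vectors", {
  # exhaustive over all confusion matrices with n <= 12
  parts <- do.call(rbind, lapply(2:12, function(n) {
    g <- expand.grid(tp = 0:n, fn = 0:n, tn = 0:n)
    g <- g[rowSums(g) <= n, ]
    g$fp <- n - rowSums(g)
    g
  }))
  got <- metric_from_confusion(tibble::as_tibble(parts), "MCC")$value
  oracle <- vapply(seq_len(nrow(parts)), function(i) {
    lab <- labels_from_cm(parts$tp[i], parts$fn[i], parts$tn[i], parts$fp[i])
    suppressWarnings(cor(lab$truth, lab$estimate))
  }, numeric(1))
  expect_equal(is.na(got), is.na(oracle))
  expect_equal(got[!is.na(got)], oracle[!is.na(oracle)], tolerance = 1e-12)
})

test_that("F1 is strictly increasing in prevalence at fixed TPR and TNR", {
  phis <- seq(0.02, 0.98, by = 0.02)
  set.seed(5)
  for (rep in 1:20) {
    tpr <- runif(1, 0.05, 0.99)
    tnr <- runif(1, 0.05, 0.99)
    f1 <- metric_from_rates(
      tibble::tibble(n = 1000, phi = phis, tpr = tpr, tnr = tnr), "F1")
    expect_true(all(diff(f1$value) > 0))
  }
})

test_that("accuracy is a convex combination of TPR and TNR", {
  set.seed(31)
  cm <- random_confusions(300, min_count = 1)
  r <- as_rates(cm)
  acc <- metric_from_rates(r, "accuracy")$value
  expect_true(all(acc >= pmin(r$tpr, r$tnr) - 1e-12))
  expect_true(all(acc <= pmax(r$tpr, r$tnr) + 1e-12))
})

test_that("the catalogue identifies orientations and the core set", {
  cat <- metric_catalogue()
  expect_setequal(cat$metric[cat$orientation == "lower"],
                  c("FN", "FP", "FPR", "FNR", "FOR", "FDR"))
  expect_length(core_metrics(), 18)
  expect_true(all(sensitive_metrics() %in% core_metrics()))
  # user-specified beta instantiates additional F-scores
  expect_true("F3" %in% metric_catalogue(beta = 3)$metric)
  f3 <- metric_from_confusion(confusion_matrix(4, 1, 3, 2), "F3")
  ppv <- 4 / 6; tpr <- 4 / 5
  expect_equal(f3$value, 10 * ppv * tpr / (9 * ppv + tpr))
})
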