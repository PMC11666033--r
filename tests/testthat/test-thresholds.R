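test_that("threshold sequences start at 0.5 and grow outward", {
  preds <- scored_predictions(c(1, 0, 1), c(0.2, 0.7, 0.7))
  expect_equal(threshold_sequence(preds), c(0.5, 0.7, 0.2))
  expect_equal(threshold_sequence(scored_predictions(1, 0.5)), 0.5)
  # distance ties break toward the smaller threshold
  tie <- scored_predictions(c(1, 0), c(0.4, 0.6))
  expect_equal(threshold_sequence(tie), c(0.5, 0.4, 0.6))
  set.seed(21)
  many <- scored_predictions(rbinom(50, 1, 0.5), round(runif(50), 2))
  th <- threshold_sequence(many)
  n_distinct <- length(unique(many$score))
  expect_true(length(th) %in% c(n_distinct, n_distinct + 1))
  expect_equal(th[1], 0.5)
  expect_true(all(diff(abs(th - 0.5)) >= 0))
  grid <- threshold_sequence(many, mode = "uniform-grid", n_grid = 11)
  expect_equal(sort(grid), seq(0, 1, by = 0.1))
})

test_that("threshold grid matches direct thresholding and is monotone", {
  set.seed(22)
  scores <- tibble::tibble(
    iteration = 0L, prevalence = 0.5, model = "GLM",
    preds = list(scored_predictions(rbinom(80, 1, 0.5), round(runif(80), 2)))
  )
  grid <- metric_threshold_grid(scores, c("TPR", "TNR", "PPV", "AUC"))
  preds <- scores$preds[[1]]
  # spot-check against the one-threshold path
  th_used <- sort(unique(grid$threshold))
  for (t in c(0.5, th_used[2], th_used[length(th_used) - 1])) {
    direct <- metric_from_confusion(
      confusion_at_threshold(preds, t)[, c("tp", "fn", "tn", "fp")],
      c("TPR", "TNR", "PPV"))
    got <- dplyr::filter(grid, .data$threshold == t, .data$metric != "AUC")
    expect_equal(got$value, direct$value)
  }
  by_t <- dplyr::arrange(grid, .data$threshold)
  expect_true(all(diff(by_t$value[by_t$metric == "TPR"]) <= 0))
  expect_true(all(diff(by_t$value[by_t$metric == "TNR"]) >= 0))
  tpr0 <- by_t$value[by_t$metric == "TPR" & by_t$threshold == min(by_t$threshold)]
  expect_equal(tpr0, 1)
  # AUC cells are constant across the whole grid
  aucs <- grid$value[grid$metric == "AUC"]
  expect_equal(length(unique(aucs)), 1)
  expect_equal(aucs[1], auc_rank(preds))
})

test_that("incremental averaging reduces to the single-threshold variance at prefix 1", {
  set.seed(23)
  scores <- purrr::map_dfr(1:4, function(i) tibble::tibble(
    iteration = i, prevalence = 0.3 + 0.1 * i, model = "GLM",
    preds = list(scored_predictions(c(0, 1, rbinom(60, 1, 0.3 + 0.1 * i)),
                                    round(runif(62), 2)))
  ))
  grid <- metric_threshold_grid(scores, c("TPR", "AUC"))
  curve <- incremental_average(grid)
  single <- evaluate_predictions(scores, c("TPR", "AUC"))
  v1 <- dplyr::filter(curve, .data$n_thresholds == 1)
  expect_equal(v1$variance[v1$metric == "TPR"],
               var(single$value[single$metric == "TPR"]))
  # AUC is identical for every prefix: a perfectly flat curve
  auc_curve <- dplyr::filter(curve, .data$metric == "AUC")
  expect_equal(diff(range(auc_curve$variance)), 0)
  expect_true(all(diff(auc_curve$n_thresholds) == 1))
  expect_true(all(curve$n_skipped == 0))
})

test_that("undefined cells are skipped, not imputed, in the averages", {
  preds <- scored_predictions(c(1, 1, 0), c(0.9, 0.6, 0.2))
  scores <- tibble::tibble(iteration = 1L, prevalence = 2 / 3, model = "m",
                           preds = list(preds))
  grid <- metric_threshold_grid(scores, "PPV")
  # at the largest threshold nothing is called positive only if t > max score;
  # all thresholds are attained scores here, so PPV stays defined
  expect_true(all(!is.na(grid$value)))
  # force an undefined cell with the strict rule at the top score
  cm <- confusion_at_threshold(preds, 0.9, rule = "gt")
  expect_true(is.na(metric_from_confusion(
    cm[, c("tp", "fn", "tn", "fp")], "PPV")$value))
})

test_that("OLS slopes detect decreasing, flat and exact-linear curves", {
  lin <- tibble::tibble(metric = "TPR", model = "A",
                        n_thresholds = 1:20,
                        variance = 2 - 0.05 * (1:20))
  s <- ols_slope(lin)
  expect_equal(s$slope, -0.05, tolerance = 1e-12)
  expect_lt(s$p.value, 1e-10)
  flat <- tibble::tibble(metric = "AUC", model = "A",
                         n_thresholds = 1:20, variance = 0.3)
  sf <- ols_slope(flat)
  expect_equal(sf$slope, 0, tolerance = 1e-14)
  expect_equal(sf$p.value, 1)
  short <- tibble::tibble(metric = "x", model = "A",
                          n_thresholds = 1:2, variance = c(1, 2))
  expect_true(is.na(ols_slope(short)$slope))
})
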