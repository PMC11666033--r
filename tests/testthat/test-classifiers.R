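test_that("train/test split has the right sizes and is seed-reproducible", {
  set.seed(4)
  d <- make_null(10)
  parts <- split_train_test(d, 0.8, seed = 1)
  expect_equal(nrow(parts$train), 8)
  expect_equal(nrow(parts$test), 2)
  again <- split_train_test(d, 0.8, seed = 1)
  expect_identical(parts$train, again$train)
  expect_error(split_train_test(d, 1.2), "between 0 and 1")
  big <- counts_dataset(2775, 3439)
  parts <- split_train_test(big, 0.8, seed = 2)
  expect_equal(nrow(parts$train), 4971)
  expect_equal(nrow(parts$test), 1243)
})

test_that("every family separates linearly separable data perfectly", {
  set.seed(10)
  d <- make_separable(240)
  parts <- split_train_test(d, 0.8, seed = 1)
  for (fam in c("GLM", "RF", "KNN", "LDA", "GBM")) {
    preds <- fit_predict(parts$train, parts$test, fam,
                         grid = utils::head(default_grid(fam), 1), seed = 3)
    expect_true(all(preds$score >= 0 & preds$score <= 1))
    expect_equal(auc_rank(preds), 1, info = fam)
  }
})

test_that("scores carry no signal when features are uninformative", {
  set.seed(20)
  d <- make_null(5000)
  parts <- split_train_test(d, 0.8, seed = 1)
  preds <- fit_predict(parts$train, parts$test, "GLM", seed = 1)
  expect_lt(abs(auc_rank(preds) - 0.5), 0.05)
})

test_that("fit_predict is deterministic given a seed and selects by CV", {
  set.seed(30)
  d <- make_separable(150)
  d$x1 <- d$x1 + rnorm(150, sd = 4)   # make the task non-trivial
  parts <- split_train_test(d, 0.8, seed = 5)
  for (fam in c("GLM", "RF", "GBM")) {
    a <- fit_predict(parts$train, parts$test, fam, cv_folds = 3, seed = 11)
    b <- fit_predict(parts$train, parts$test, fam, cv_folds = 3, seed = 11)
    expect_identical(a, b, info = fam)
  }
  expect_error(fit_predict(parts$train[parts$train$label == 1, ],
                           parts$test, "GLM"), "both classes")
  expect_error(fit_predict(parts$train, parts$test, "SVM"), "unsupported")
})

test_that("random guess assigns exactly round(phi * n) positive calls", {
  rg <- random_guess(rep(c(1, 0), c(6, 4)), phi = 0.6, seed = 1)
  expect_equal(sum(rg$score >= 0.51 & rg$score <= 0.99), 6)
  expect_equal(sum(rg$score >= 0.01 & rg$score <= 0.49), 4)
  all_pos <- random_guess(rbinom(20, 1, 0.5), phi = 1, seed = 2)
  expect_true(all(all_pos$score >= 0.51))
  # the positive calls land on uniformly random rows
  expect_identical(random_guess(rep(1, 5), phi = 0.4, seed = 9),
                   random_guess(rep(1, 5), phi = 0.4, seed = 9))
})

test_that("random-guess accuracy concentrates at phi^2 + (1 - phi)^2", {
  phi <- 0.452
  set.seed(123)
  labels <- rbinom(1000, 1, phi)
  accs <- vapply(1:150, function(s) {
    rg <- random_guess(labels, seed = s)
    cm <- confusion_at_threshold(rg, 0.5)
    (cm$tp + cm$tn) / 1000
  }, numeric(1))
  phi_real <- mean(labels)
  expected <- phi_real^2 + (1 - phi_real)^2
  expect_lt(abs(mean(accs) - expected), 3 * sd(accs) / sqrt(length(accs)) + 0.005)
})

test_that("chance-corrected metrics center on zero for random guessing", {
  set.seed(99)
  labels <- rbinom(400, 1, 0.45)
  vals <- purrr::map_dfr(1:200, function(s) {
    rg <- random_guess(labels, seed = s)
    cm <- confusion_at_threshold(rg, 0.5)
    metric_from_confusion(cm[, c("tp", "fn", "tn", "fp")],
                          c("BI", "MCC", "kappa"))
  })
  by_metric <- dplyr::summarise(
    dplyr::group_by(vals, .data$metric),
    m = mean(.data$value), se = sd(.data$value) / sqrt(dplyr::n())
  )
  expect_true(all(abs(by_metric$m) < 3 * by_metric$se))
})

test_that("every trained family beats random guess in AUC on synthetic data", {
  d <- generate_dataset(generator_config(n = 2500, seed = 61))
  parts <- split_train_test(d, 0.8, seed = 6)
  rg_auc <- auc_rank(fit_predict(parts$train, parts$test, "random_guess",
                                 seed = 7))
  for (fam in c("GLM", "RF", "KNN", "LDA", "GBM")) {
    preds <- fit_predict(parts$train, parts$test, fam,
                         grid = utils::head(default_grid(fam), 1), seed = 7)
    expect_gt(auc_rank(preds), rg_auc + 0.05)
  }
})
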