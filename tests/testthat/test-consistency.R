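test_that("average-tie ranking reproduces the published rank rows", {
  # accuracy row: higher is better
  expect_equal(rank_values(c(0.689, 0.667, 0.657, 0.667, 0.687, 0.525)),
               c(1, 3.5, 5, 3.5, 2, 6))
  # false-negative counts: lower is better
  expect_equal(rank_values(c(223, 270, 266, 276, 251, 295), "lower"),
               c(1, 4, 3, 5, 2, 6))
  expect_equal(rank_values(rep(0.5, 6)), rep(3.5, 6))
  # undefined values rank last, ties averaged
  expect_equal(rank_values(c(0.9, NA, 0.7, NA)), c(1, 3.5, 2, 3.5))
  expect_error(rank_values(c(NA_real_, NA_real_)), "all values undefined")
})

test_that("rank rows sum to m(m+1)/2 and reverse with orientation", {
  set.seed(14)
  for (i in 1:50) {
    m <- sample(3:8, 1)
    x <- sample(round(runif(m), 2), m)  # duplicates likely
    hi <- rank_values(x, "higher")
    lo <- rank_values(x, "lower")
    expect_equal(sum(hi), m * (m + 1) / 2)
    expect_equal(sort(hi + lo), sort(rep(m + 1, m)))
  }
})

test_that("evaluate_predictions fills the grid with tagged cells", {
  set.seed(15)
  d <- make_separable(160)
  sw <- run_sweep(d, k = 8, down_iters = 1, up_iters = 1, seed = 3)
  grid <- evaluate_grid(sw, models = fast_specs(c("GLM", "random_guess")),
                        metrics = c("accuracy", "TPR", "AUC"), seed = 9)
  expect_s3_class(grid, "evaluation_grid")
  expect_equal(nrow(grid), 3 * 2 * 3)
  expect_true(all(grid$value[grid$metric == "accuracy"] >= 0 &
                    grid$value[grid$metric == "accuracy"] <= 1))
  # separable data: trained model attains AUC 1 on every dataset
  expect_true(all(grid$value[grid$metric == "AUC" & grid$model == "GLM"] == 1))
  expect_identical(names(sweep_predictions(grid)),
                   c("iteration", "prevalence", "test_prevalence", "model",
                     "preds"))
  g <- glance(grid)
  expect_equal(g$n_datasets, 3)
  expect_equal(g$n_models, 2)
})

test_that("ranking variance has closed-form values on constructed grids", {
  grid <- tibble::tibble(
    iteration = rep(1:2, each = 2),
    model = rep(c("A", "B"), 2),
    metric = "accuracy",
    value = c(0.9, 0.8, 0.7, 0.9)   # ranks (1,2) then (2,1)
  )
  class(grid) <- c("evaluation_grid", class(grid))
  v <- ranking_variance(grid)
  expect_equal(v$var_rank, c(0.5, 0.5))
  expect_equal(v$var_value, c(var(c(0.9, 0.7)), var(c(0.8, 0.9))))
  # constant ranks give zero variance; order of datasets is irrelevant
  const <- grid
  const$value <- c(0.9, 0.8, 0.9, 0.8)
  expect_equal(ranking_variance(const)$var_rank, c(0, 0))
  shuffled <- grid[c(3, 4, 1, 2), ]
  expect_equal(ranking_variance(shuffled), ranking_variance(grid))
  expect_error(ranking_variance(grid[grid$iteration == 1, ]),
               "at least two datasets")
})

test_that("variance-homogeneity tests behave on canonical inputs", {
  # equal-variance groups: Levene far from rejection
  set.seed(16)
  same <- tibble::tibble(
    metric = rep(c("TPR", "MCC"), each = 80),
    model = "A",
    value = rep(rnorm(80), 2)
  )
  out <- variance_equality_tests(same)
  expect_s3_class(out, "variance_test_results")
  expect_gt(out$p.value[out$test == "Levene"], 0.9)
  expect_gt(out$p.value[out$test == "F"], 0.9)
  # N(0,1) vs N(0,9): all three tests reject decisively
  set.seed(17)
  diff <- tibble::tibble(
    metric = rep(c("TPR", "MCC"), each = 200),
    model = "A",
    value = c(rnorm(200, sd = 3), rnorm(200, sd = 1))
  )
  out2 <- variance_equality_tests(diff)
  expect_true(all(out2$p.value < 0.05))
  expect_gt(out2$var_ratio[1], 1)
  expect_error(variance_equality_tests(same, sensitive = "F1"),
               "non-empty")
})

test_that("rank_models applies per-metric orientation within each dataset", {
  grid <- tibble::tibble(
    iteration = 1L, prevalence = 0.5,
    model = rep(c("A", "B", "C"), 2),
    metric = rep(c("accuracy", "FN"), each = 3),
    value = c(0.9, 0.8, 0.7, 10, 20, 30)
  )
  class(grid) <- c("evaluation_grid", class(grid))
  r <- rank_models(grid)
  expect_equal(r$rank[r$metric == "accuracy"], c(1, 2, 3))
  expect_equal(r$rank[r$metric == "FN"], c(1, 2, 3))  # fewer misses is better
})
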