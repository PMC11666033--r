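smoke_config <- function(out_dir, seed = 5) {
  study_config(
    generator = generator_config(n = 400, seed = 99),
    k = 10, down_iters = 2, up_iters = 2,
    models = fast_specs(c("GLM", "random_guess")),
    metrics = c("accuracy", "TPR", "TNR", "F1", "MCC", "AUC"),
    out_dir = out_dir, seed = seed
  )
}

test_that("run_study writes the complete artifact bundle", {
  out <- withr::local_tempdir()
  study <- suppressWarnings(run_study(smoke_config(out), quiet = TRUE))
  expect_s3_class(study, "metric_study")
  files <- c("sweep_schedule.csv", "correlation_drift.csv",
             "metric_values.csv", "model_ranks.csv", "variance_table.csv",
             "variance_tests.csv", "threshold_grid.csv",
             "threshold_curves.csv", "threshold_slopes.csv",
             "manifest.json", "summary.json")
  expect_true(all(file.exists(file.path(out, files))))
  expect_equal(nrow(study$sweep), 5)
  expect_equal(nrow(study$grid), 5 * 2 * 6)
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$n_datasets, 5)
  expect_equal(manifest$seed, 5)
  expect_output(print(study), "metric_study")
})

test_that("identical seeds give byte-identical study outputs", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  suppressWarnings(run_study(smoke_config(out1), quiet = TRUE))
  suppressWarnings(run_study(smoke_config(out2), quiet = TRUE))
  for (f in c("metric_values.csv", "model_ranks.csv", "threshold_curves.csv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
  out3 <- withr::local_tempdir()
  other <- suppressWarnings(run_study(smoke_config(out3, seed = 6), quiet = TRUE))
  expect_false(identical(
    readLines(file.path(out1, "metric_values.csv")),
    readLines(file.path(out3, "metric_values.csv"))
  ))
})

test_that("tidiers and autoplot methods cover the result types", {
  out <- withr::local_tempdir()
  study <- suppressWarnings(run_study(smoke_config(out), quiet = TRUE))
  td <- tidy(study)
  expect_true(all(c("iteration", "model", "metric", "value") %in% names(td)))
  g <- glance(study)
  expect_equal(g$n_datasets, 5)
  expect_true(g$most_consistent_metric %in% unique(td$metric))
  expect_s3_class(autoplot(study$grid), "ggplot")
  expect_s3_class(autoplot(study$ranks), "ggplot")
  expect_s3_class(autoplot(study$variances), "ggplot")
  expect_s3_class(autoplot(study$curves), "ggplot")
  expect_s3_class(autoplot(study$sweep), "ggplot")
})

test_that("study configs load from YAML with validation", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "generator:", "  n: 300", "  seed: 2",
    "k: 5", "down_iters: 1", "up_iters: 1",
    "models: [GLM, random_guess]", "seed: 4"
  ), path)
  cfg <- study_config_from_file(path)
  expect_s3_class(cfg, "study_config")
  expect_equal(cfg$generator$n, 300)
  expect_equal(cfg$k, 5)
  expect_setequal(names(cfg$models), c("GLM", "random_guess"))
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("nonsense: 1", bad)
  expect_error(study_config_from_file(bad), "unknown config keys")
})

test_that("labelled CSVs round-trip through the reader", {
  d <- generate_dataset(generator_config(n = 120, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(d, path)
  back <- read_labelled_csv(path)
  expect_equal(dim(back), dim(d))
  expect_s3_class(back$crime_charge, "factor")
  expect_equal(back$label, d$label)
  nolab <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(d, -"label"), nolab)
  expect_error(read_labelled_csv(nolab), "label")
  sp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(scored_predictions(c(1, 0, 1), c(0.9, 0.2, 0.6)), sp)
  expect_equal(read_scored_csv(sp),
               scored_predictions(c(1, 0, 1), c(0.9, 0.2, 0.6)))
})
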