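# Model fitting behind a single fit/predict surface. A dataset is a tibble
# with a binary `label` column plus feature columns (numeric or factor).

validate_dataset <- function(data, need_both_classes = FALSE) {
  if (!"label" %in% names(data)) stop("dataset needs a `label` column")
  check_binary(data$label, "label")
  if (ncol(data) < 1 || nrow(data) < 1) stop("empty dataset")
  if (need_both_classes && length(unique(data$label)) < 2) {
    stop("dataset must contain both classes")
  }
  invisible(data)
}

#' Split a dataset into training and test parts
#'
#' Random disjoint row partition with `round(train_fraction * n)` training
#' rows; with the study default of 0.8 and n = 6214 this yields 4971 training
#' and 1243 test rows.
#'
#' @param data Dataset tibble with a `label` column.
#' @param train_fraction Fraction of rows assigned to training, in (0, 1).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(data, train_fraction = 0.8, seed = NULL) {
  validate_dataset(data)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  n <- nrow(data)
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train >= n) stop("split leaves an empty part")
  idx <- with_seed_if(seed, sample.int(n, n_train))
  list(train = data[idx, , drop = FALSE],
       test = data[-idx, , drop = FALSE])
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Default hyperparameter grids for the model families
#'
#' Small deliberate grids: the study's claims concern metric behavior across
#' prevalence, not model tuning, so the grids only give cross-validation
#' something real to select over.
#'
#' @param family One of `"GLM"`, `"RF"`, `"KNN"`, `"LDA"`, `"GBM"`.
#' @return A data frame with one row per hyperparameter combination (a
#'   zero-column one-row frame for families without tunable parameters).
#' @export
default_grid <- function(family) {
  switch(family,
    GLM = data.frame(row.names = 1),
    LDA = data.frame(row.names = 1),
    RF = data.frame(num_trees = c(100, 300)),
    KNN = data.frame(k = c(5, 15, 31)),
    GBM = expand.grid(max_depth = c(1, 3), eta = 0.1, nrounds = 100),
    stop("unsupported family: ", family)
  )
}

model_families <- function() c("GLM", "RF", "KNN", "LDA", "GBM")

#' Default model specifications for the study
#'
#' The five learner families plus the prevalence-matched random-guess
#' baseline.
#'
#' @param families Families to include.
#' @param grids Named list overriding [default_grid()] per family.
#' @param cv_folds Cross-validation folds used for hyperparameter selection.
#' @return Named list of specs consumed by [fit_predict()] and
#'   [score_sweep()].
#' @export
default_model_specs <- function(families = c(model_families(), "random_guess"),
                                grids = list(), cv_folds = 10) {
  specs <- lapply(families, function(f) {
    if (f == "random_guess") {
      list(family = "random_guess")
    } else {
      list(family = f,
           grid = grids[[f]] %||% default_grid(f),
           cv_folds = cv_folds)
    }
  })
  names(specs) <- families
  specs
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# ---- feature encoding -------------------------------------------------------

# One-hot encode factors/characters with training-set levels; optionally
# standardize columns by training mean/sd (distance- and projection-based
# families). Constant training columns are dropped.
encode_features <- function(train, test, standardize = FALSE) {
  feats <- setdiff(names(train), "label")
  tr <- train[feats]
  te <- test[feats]
  for (f in feats) {
    if (is.character(tr[[f]]) || is.factor(tr[[f]])) {
      lev <- levels(factor(tr[[f]]))
      tr[[f]] <- factor(tr[[f]], levels = lev)
      te[[f]] <- factor(te[[f]], levels = lev)
    }
  }
  mm <- function(d) model.matrix(~ . - 1, data = d,
                                 contrasts.arg = NULL)
  xtr <- mm(tr)
  xte <- mm(te)
  keep <- intersect(colnames(xtr), colnames(xte))
  xtr <- xtr[, keep, drop = FALSE]
  xte <- xte[, keep, drop = FALSE]
  sds <- apply(xtr, 2, sd)
  keep <- sds > 0
  xtr <- xtr[, keep, drop = FALSE]
  xte <- xte[, keep, drop = FALSE]
  if (standardize) {
    mu <- colMeans(xtr)
    s <- sds[keep]
    xtr <- scale(xtr, center = mu, scale = s)
    xte <- scale(xte, center = mu, scale = s)
  }
  list(train = xtr, test = xte)
}

# ---- family fit/predict -----------------------------------------------------

fit_predict_family <- function(family, params, train, test, seed = NULL) {
  y <- train$label
  out <- switch(family,
    GLM = {
      fit <- suppressWarnings(
        stats::glm(label ~ ., data = train, family = stats::binomial())
      )
      suppressWarnings(as.numeric(predict(fit, newdata = test,
                                          type = "response")))
    },
    LDA = {
      enc <- encode_features(train, test, standardize = TRUE)
      fit <- suppressWarnings(MASS::lda(enc$train, grouping = factor(y)))
      as.numeric(predict(fit, enc$test)$posterior[, "1"])
    },
    RF = {
      df <- train
      df$label <- factor(df$label, levels = c(0, 1))
      fit <- ranger::ranger(
        label ~ ., data = df, probability = TRUE,
        num.trees = params$num_trees %||% 300,
        seed = if (is.null(seed)) 0L else as.integer(seed),
        num.threads = 1
      )
      as.numeric(predict(fit, data = test,
                         num.threads = 1)$predictions[, "1"])
    },
    KNN = {
      enc <- encode_features(train, test, standardize = TRUE)
      pred <- with_seed_if(seed %||% 0L,
        class::knn(enc$train, enc$test, cl = factor(y),
                   k = params$k %||% 15, prob = TRUE)
      )
      p_win <- attr(pred, "prob")
      ifelse(pred == "1", p_win, 1 - p_win)
    },
    GBM = {
      enc <- encode_features(train, test, standardize = FALSE)
      dtr <- xgboost::xgb.DMatrix(enc$train, label = y)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth %||% 3,
                      eta = params$eta %||% 0.1,
                      nthread = 1, seed = if (is.null(seed)) 0L else as.integer(seed)),
        data = dtr, nrounds = params$nrounds %||% 100, verbose = 0
      )
      as.numeric(predict(fit, xgboost::xgb.DMatrix(enc$test)))
    },
    stop("unsupported family: ", family)
  )
  pmin(pmax(out, 0), 1)
}

stratified_folds <- function(labels, k, seed = NULL) {
  with_seed_if(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

#' Fit a classifier with cross-validated hyperparameters and score a test set
#'
#' Hyperparameters are selected by k-fold cross-validation on the training
#' data over the spec's grid, scoring each combination by mean validation
#' AUC; the winning combination is refit on the full training data and used
#' to score the test rows with positive-class probabilities. A grid with a
#' single row skips the cross-validation loop (there is nothing to select).
#'
#' @param train,test Dataset tibbles with a binary `label` column.
#' @param family Model family: `"GLM"` (logistic regression), `"RF"` (random
#'   forest), `"KNN"`, `"LDA"`, `"GBM"` (gradient boosting), or
#'   `"random_guess"` for the prevalence-matched baseline.
#' @param grid Hyperparameter grid (data frame, one row per combination);
#'   defaults to [default_grid()].
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fitting; the same seed reproduces identical scores.
#' @return A scored-predictions tibble: the test `label` column plus `score`.
#' @export
fit_predict <- function(train, test, family, grid = NULL, cv_folds = 10,
                        seed = NULL) {
  validate_dataset(test)
  if (family == "random_guess") {
    return(random_guess(test$label, seed = seed))
  }
  validate_dataset(train, need_both_classes = TRUE)
  if (is.null(grid)) grid <- default_grid(family)
  if (!is.data.frame(grid) || nrow(grid) < 1) stop("grid must be non-empty")
  best <- 1L
  if (nrow(grid) > 1) {
    if (cv_folds < 2) stop("cv_folds must be at least 2")
    fold <- stratified_folds(train$label, cv_folds, seed = seed)
    cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
      aucs <- vapply(seq_len(cv_folds), function(f) {
        tr <- train[fold != f, , drop = FALSE]
        va <- train[fold == f, , drop = FALSE]
        if (length(unique(va$label)) < 2) return(NA_real_)
        sc <- fit_predict_family(family, as.list(grid[g, , drop = FALSE]),
                                 tr, va, seed = seed)
        auc_rank(scored_predictions(va$label, sc))
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(cv_auc)
  }
  score <- fit_predict_family(family, as.list(grid[best, , drop = FALSE]),
                              train, test, seed = seed)
  scored_predictions(test$label, score)
}

#' Prevalence-matched random-guess baseline
#'
#' Randomly assigns predicted class labels so that exactly
#' `round(phi * n)` cases are called positive, then draws the predicted
#' positive-class probability uniformly from `[0.51, 0.99]` for cases called
#' positive and from `[0.01, 0.49]` for cases called negative. With `phi`
#' equal to the realized test-set prevalence this is the naive baseline every
#' informative model should beat.
#'
#' @param test_labels Binary vector of true test labels.
#' @param phi Proportion of cases to call positive; defaults to the realized
#'   prevalence of `test_labels`.
#' @param seed Integer seed.
#' @return A scored-predictions tibble (`label` = true labels, `score` =
#'   random-guess probabilities).
#' @export
random_guess <- function(test_labels, phi = NULL, seed = NULL) {
  test_labels <- check_binary(test_labels, "test_labels")
  n <- length(test_labels)
  if (is.null(phi)) phi <- mean(test_labels)
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  n_pos <- round(phi * n)
  with_seed_if(seed, {
    called_pos <- sample.int(n) <= n_pos
    score <- ifelse(called_pos, runif(n, 0.51, 0.99), runif(n, 0.01, 0.49))
    scored_predictions(test_labels, score)
  })
}
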