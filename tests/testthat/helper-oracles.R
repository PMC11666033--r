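# Independent oracles and fixture builders used across the suite.

# AUC by enumeration of all positive-negative pairs (ties credited 0.5)
auc_brute <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(pairs)
}

# expand a confusion matrix into the label vectors that generate it
labels_from_cm <- function(tp, fn, tn, fp) {
  list(
    truth = c(rep(1, tp + fn), rep(0, tn + fp)),
    estimate = c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  )
}

random_confusions <- function(n_draws, max_count = 60, min_count = 0) {
  tibble::tibble(
    tp = sample(min_count:max_count, n_draws, replace = TRUE),
    fn = sample(min_count:max_count, n_draws, replace = TRUE),
    tn = sample(min_count:max_count, n_draws, replace = TRUE),
    fp = sample(min_count:max_count, n_draws, replace = TRUE)
  ) |>
    dplyr::filter(.data$tp + .data$fn + .data$tn + .data$fp > 0)
}

# linearly separable two-feature dataset
make_separable <- function(n = 200) {
  label <- rep(c(0, 1), length.out = n)
  tibble::tibble(
    x1 = rnorm(n, mean = ifelse(label == 1, 4, -4), sd = 0.5),
    x2 = rnorm(n, mean = ifelse(label == 1, -4, 4), sd = 0.5),
    label = label
  )
}

# features carry no information about the label
make_null <- function(n = 200, prevalence = 0.5) {
  tibble::tibble(
    x1 = rnorm(n), x2 = rnorm(n),
    label = rbinom(n, 1, prevalence)
  )
}

# minimal dataset with exact class counts, for sweep arithmetic
counts_dataset <- function(n_pos, n_neg) {
  n <- n_pos + n_neg
  tibble::tibble(
    x1 = rnorm(n), x2 = rnorm(n),
    label = c(rep(1, n_pos), rep(0, n_neg))
  )
}

fast_specs <- function(families = c("GLM", "random_guess")) {
  grids <- list(RF = data.frame(num_trees = 100),
                KNN = data.frame(k = 15),
                GBM = data.frame(max_depth = 3, eta = 0.1, nrounds = 60))
  default_model_specs(families = families, grids = grids)
}
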