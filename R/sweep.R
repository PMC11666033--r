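# Constant-n prevalence sweep: repeatedly swap k cases between classes so the
# prevalence walks up or down while the sample size and the inter-variable
# relationships stay (approximately) fixed.

class_counts <- function(data) {
  pos <- sum(data$label == 1)
  c(pos = pos, neg = nrow(data) - pos)
}

#' One class-swap step
#'
#' Removes `k` uniformly sampled members of the shrinking class (without
#' replacement) and adds `k` members to the growing class, sampled with
#' replacement from `pool` (defaults to `data` itself). Stepping `"down"`
#' shrinks the positive class; `"up"` shrinks the negative class. The sample
#' size is unchanged by construction.
#'
#' @param data Dataset tibble with a binary `label` column.
#' @param direction `"down"` (prevalence decreases) or `"up"`.
#' @param k Number of cases swapped.
#' @param pool Dataset supplying the added cases (e.g. the original dataset
#'   to limit duplication cascades); defaults to `data`.
#' @return The rebalanced dataset tibble.
#' @export
swap_step <- function(data, direction = c("down", "up"), k, pool = NULL) {
  direction <- match.arg(direction)
  validate_dataset(data)
  if (is.null(pool)) pool <- data
  stopifnot(k >= 0)
  if (k == 0) return(data)
  shrink_label <- if (direction == "down") 1 else 0
  grow_label <- 1 - shrink_label
  shrink_idx <- which(data$label == shrink_label)
  grow_pool <- which(pool$label == grow_label)
  if (length(shrink_idx) <= k) {
    stop("class exhaustion: shrinking class has ", length(shrink_idx),
         " members, cannot remove ", k)
  }
  if (length(grow_pool) == 0) stop("pool has no members of the growing class")
  drop_idx <- shrink_idx[sample.int(length(shrink_idx), k)]
  add_idx <- grow_pool[sample.int(length(grow_pool), k, replace = TRUE)]
  dplyr::bind_rows(data[-drop_idx, , drop = FALSE],
                   pool[add_idx, , drop = FALSE])
}

#' Run the full prevalence sweep
#'
#' Starting from the original dataset, chains [swap_step()] cumulatively
#' `down_iters` times downward and, independently from the original again,
#' `up_iters` times upward. With the study defaults (k = 30, 76 downward and
#' 79 upward iterations from 2775 positives / 3439 negatives) this produces
#' 156 datasets whose positive counts follow the exact schedule
#' `pos0 - 30 * i` down to 495 and `pos0 + 30 * i` up to 5145.
#'
#' @param data Dataset tibble with a binary `label` column.
#' @param k Cases swapped per iteration.
#' @param down_iters,up_iters Number of iterations per arm. Bounded so that
#'   no class is exhausted.
#' @param pool `"original"` (default) draws added cases with replacement from
#'   the original class pool; `"current"` draws from the evolving dataset.
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @param saturation_eps Optional saturation stop (off by default): when a
#'   number in (0, 1), each arm stops early once a logistic regression fit on
#'   an 80/20 split of the current dataset reaches TPR below `saturation_eps`
#'   (downward arm) or TNR below it (upward arm), mirroring the rationale of
#'   fixed iteration counts chosen where the rates flatten out.
#' @return A `sweep_series` tibble with one row per dataset: `iteration`
#'   (negative on the downward arm, 0 for the original), `n_pos`, `n_neg`,
#'   `prevalence`, and the dataset in the `data` list-column.
#' @export
run_sweep <- function(data, k = 30, down_iters = 76, up_iters = 79,
                      pool = c("original", "current"), seed = NULL,
                      saturation_eps = NULL) {
  pool <- match.arg(pool)
  validate_dataset(data)
  cc <- class_counts(data)
  if (k * down_iters >= cc["pos"]) {
    stop("k * down_iters must be smaller than the initial positive count")
  }
  if (k * up_iters >= cc["neg"]) {
    stop("k * up_iters must be smaller than the initial negative count")
  }
  saturated <- function(d, direction) {
    if (is.null(saturation_eps)) return(FALSE)
    parts <- split_train_test(d, 0.8)
    preds <- fit_predict(parts$train, parts$test, "GLM")
    cm <- confusion_at_threshold(preds, 0.5)
    rate <- if (direction == "down") {
      cm$tp / (cm$tp + cm$fn)
    } else {
      cm$tn / (cm$tn + cm$fp)
    }
    is.finite(rate) && rate < saturation_eps
  }
  walk_arm <- function(direction, iters) {
    out <- vector("list", iters)
    current <- data
    for (i in seq_len(iters)) {
      current <- swap_step(current, direction, k,
                           pool = if (pool == "original") data else NULL)
      out[[i]] <- current
      if (saturated(current, direction)) {
        out <- out[seq_len(i)]
        break
      }
    }
    out
  }
  arms <- with_seed_if(seed, list(down = walk_arm("down", down_iters),
                                  up = walk_arm("up", up_iters)))
  n_down <- length(arms$down)
  n_up <- length(arms$up)
  datasets <- c(rev(arms$down), list(data), arms$up)
  iteration <- c(-rev(seq_len(n_down)), 0L,
                 if (n_up > 0) seq_len(n_up) else integer())
  counts <- vapply(datasets, class_counts, numeric(2))
  out <- tibble::tibble(
    iteration = as.integer(iteration),
    n_pos = as.integer(counts["pos", ]),
    n_neg = as.integer(counts["neg", ]),
    prevalence = counts["pos", ] / colSums(counts),
    data = datasets
  )
  structure(out, class = c("sweep_series", class(out)),
            k = k, pool = pool, seed = seed)
}

#' Correlation drift along a sweep
#'
#' Quantifies how far each rebalanced dataset's pairwise correlation
#' structure (all features plus the outcome, numerically encoded) has moved
#' from the original dataset's: the maximum absolute entrywise deviation of
#' the correlation matrices. Columns that are constant in either dataset
#' have undefined correlations; their pairs are excluded and counted.
#'
#' @param sweep A `sweep_series` from [run_sweep()].
#' @return A tibble with `iteration`, `prevalence`, `max_drift` and
#'   `n_excluded` (correlation pairs dropped because a column was constant).
#' @export
correlation_drift <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_series") || all(
    c("iteration", "data") %in% names(sweep)))
  encode_numeric <- function(d) {
    out <- lapply(d, function(col) {
      if (is.character(col)) col <- factor(col)
      if (is.factor(col)) as.numeric(col) else as.numeric(col)
    })
    do.call(cbind, out)
  }
  ref_row <- which(sweep$iteration == 0)
  if (length(ref_row) != 1) stop("sweep must contain the original dataset (iteration 0)")
  ref <- encode_numeric(sweep$data[[ref_row]])
  ref_cor <- suppressWarnings(cor(ref))
  purrr::map_dfr(seq_len(nrow(sweep)), function(i) {
    m <- suppressWarnings(cor(encode_numeric(sweep$data[[i]])))
    diffs <- abs(m - ref_cor)
    excluded <- is.na(diffs)
    diag(excluded) <- FALSE
    tibble::tibble(
      iteration = sweep$iteration[i],
      prevalence = sweep$prevalence[i],
      max_drift = max(diffs[upper.tri(diffs)], na.rm = TRUE),
      n_excluded = sum(excluded[upper.tri(excluded)])
    )
  })
}
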