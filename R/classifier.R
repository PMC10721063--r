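#' Draw one bootstrap resample
#'
#' Draws `n` row indices with replacement from `n` rows using the current RNG
#' state (seed it with `set.seed()` for reproducibility) and returns the
#' resampled data. For large `n` the expected fraction of distinct rows tends
#' to `1 - 1/e`.
#'
#' @param x Feature matrix or data frame.
#' @param y Label vector aligned with `x`.
#' @return List with `x`, `y`, and the drawn `indices`.
#' @export
bootstrap_sample <- function(x, y) {
  n <- nrow(x)
  if (is.null(n) || n < 1) abort("`x` must have at least one row")
  if (length(y) != n) abort("`y` must align with the rows of `x`")
  idx <- sample.int(n, n, replace = TRUE)
  list(x = x[idx, , drop = FALSE], y = y[idx], indices = idx)
}

#' Train a bagged decision-tree ensemble
#'
#' Classic bootstrap aggregation: `n_cycles` unpruned decision trees, each fit
#' on an independent bootstrap resample of the training data. Trees are grown
#' by `rpart` with surrogate splits recorded (up to 5 per node, ranked by
#' agreement with the primary split) so prediction degrades gracefully when a
#' primary split feature is missing; on feature-complete inputs surrogates
#' are never consulted. Depth is effectively unlimited and the minimum leaf
#' size is 1.
#'
#' @param x Numeric feature matrix or data frame.
#' @param y Class labels (>= 2 classes).
#' @param n_cycles Number of trees / learning cycles (default 50).
#' @param surrogate_splits Record surrogate splits (default `TRUE`).
#' @param seed Integer seed making the resamples reproducible.
#' @param min_leaf Minimum observations per leaf (default 1).
#' @return A `bagged_ensemble`: list of `rpart` trees plus `class_order`,
#'   `n_cycles`, `seed`, and the per-tree bootstrap indices.
#' @export
train_bagging <- function(x, y, n_cycles = 50L, surrogate_splits = TRUE,
                          seed = 1L, min_leaf = 1L) {
  y <- factor(y)
  if (nlevels(y) < 2) abort("`y` must contain at least 2 classes")
  df <- as.data.frame(as.matrix(x))
  names(df) <- make.names(names(df), unique = TRUE)
  control <- rpart::rpart.control(
    minsplit = 2L, minbucket = as.integer(min_leaf), cp = 0, xval = 0L,
    maxdepth = 30L,
    maxsurrogate = if (surrogate_splits) 5L else 0L,
    usesurrogate = if (surrogate_splits) 2L else 0L
  )
  trees <- vector("list", n_cycles)
  indices <- vector("list", n_cycles)
  with_seed(derive_seed(seed, 29L), {
    for (i in seq_len(n_cycles)) {
      bs <- bootstrap_sample(df, y)
      dat <- bs$x
      dat$.class <- bs$y
      trees[[i]] <- rpart::rpart(.class ~ ., data = dat, method = "class",
                                 control = control)
      indices[[i]] <- bs$indices
    }
  })
  structure(list(trees = trees, class_order = levels(y),
                 n_cycles = as.integer(n_cycles),
                 surrogate_splits = surrogate_splits, seed = as.integer(seed),
                 feature_names = names(df), bootstrap_indices = indices),
            class = "bagged_ensemble")
}

#' Soft-voting prediction from a bagged ensemble
#'
#' Each tree emits a class-probability vector (its leaf class frequencies);
#' the ensemble probability is their arithmetic mean over the `N` trees and
#' the predicted class is the argmax,
#' \eqn{\hat y = \arg\max_c \frac{1}{N}\sum_{i=1}^{N} P(h_i(x) = c)},
#' with ties broken toward the lowest class index in `class_order`.
#'
#' @param ensemble A `bagged_ensemble`.
#' @param newdata Feature matrix or data frame with the training columns.
#' @return Tibble with one row per input: `.pred` (factor) followed by one
#'   `.prob_<class>` column per class (rows sum to 1).
#' @export
predict_soft <- function(ensemble, newdata) {
  df <- as.data.frame(as.matrix(newdata))
  names(df) <- make.names(names(df), unique = TRUE)
  if (!identical(names(df), ensemble$feature_names)) {
    if (ncol(df) != length(ensemble$feature_names)) {
      abort(paste0("newdata has ", ncol(df), " features; ensemble was ",
                   "trained on ", length(ensemble$feature_names)))
    }
    names(df) <- ensemble$feature_names
  }
  probs <- Reduce(`+`, lapply(ensemble$trees, function(tr) {
    predict(tr, newdata = df, type = "prob")
  })) / length(ensemble$trees)
  probs <- probs[, ensemble$class_order, drop = FALSE]
  pred_idx <- max.col(probs, ties.method = "first")
  out <- tibble(.pred = factor(ensemble$class_order[pred_idx],
                               levels = ensemble$class_order))
  pm <- as_tibble(as.data.frame(probs))
  names(pm) <- paste0(".prob_", ensemble$class_order)
  bind_cols(out, pm)
}

#' @export
print.bagged_ensemble <- function(x, ...) {
  cat("<bagged_ensemble>", x$n_cycles, "trees |", length(x$class_order),
      "classes | surrogate splits:", x$surrogate_splits, "\n")
  invisible(x)
}

#' @export
tidy.bagged_ensemble <- function(x, ...) {
  tibble(
    tree = seq_along(x$trees),
    n_leaves = map_int(x$trees, function(tr) sum(tr$frame$var == "<leaf>")),
    n_unique_rows = map_int(x$bootstrap_indices, function(i) length(unique(i)))
  )
}

#' @export
glance.bagged_ensemble <- function(x, ...) {
  tibble(n_cycles = x$n_cycles, n_classes = length(x$class_order),
         surrogate_splits = x$surrogate_splits, seed = x$seed)
}
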