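#' Multiclass confusion counts
#'
#' Tallies the full K x K confusion matrix and the per-class one-vs-rest
#' counts: TP (class predicted and true), FP (predicted but not true), FN
#' (true but not predicted), TN (neither). For every class
#' `TP + FP + FN + TN` equals the number of evaluated samples.
#'
#' @param truth True class labels.
#' @param estimate Predicted class labels, same length.
#' @param class_order Optional fixed class ordering; defaults to the sorted
#'   union of observed labels. Labels outside it are an error.
#' @return Tibble with columns `class`, `tp`, `fp`, `fn`, `tn` and attribute
#'   `matrix` (the K x K table, rows = truth).
#' @export
confusion_counts <- function(truth, estimate, class_order = NULL) {
  truth <- as.character(truth); estimate <- as.character(estimate)
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have the same length")
  }
  class_order <- class_order %||% sort(unique(c(truth, estimate)))
  bad <- setdiff(unique(c(truth, estimate)), class_order)
  if (length(bad)) abort(paste0("label(s) outside `class_order`: ",
                                paste(bad, collapse = ", ")))
  tf <- factor(truth, levels = class_order)
  ef <- factor(estimate, levels = class_order)
  m <- table(truth = tf, estimate = ef)
  total <- length(truth)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  out <- tibble(class = class_order,
                tp = as.integer(tp), fp = as.integer(fp),
                fn = as.integer(fn),
                tn = as.integer(total - tp - fp - fn))
  attr(out, "matrix") <- unclass(m)
  out
}

apply_rounding <- function(x, rounding) {
  switch(rounding,
         integer = round_half_up(x, 0),
         one_decimal = round_half_up(x, 1),
         none = x)
}

#' Per-class precision, sensitivity, specificity and F1
#'
#' Computes, in percent: precision `100 TP/(TP+FP)`, sensitivity
#' `100 TP/(TP+FN)`, specificity `100 TN/(TN+FP)`, and
#' `F1 = 2 P S / (P + S)` from the unrounded percentages. A zero denominator
#' yields `NA` (undefined), never 0, with the affected classes flagged in the
#' `undefined` attribute. `rounding = "integer"` (half-up) reproduces
#' published tables that print whole percentages; `"one_decimal"` matches
#' prose-style values.
#'
#' @param counts Output of [confusion_counts()], or any data frame with
#'   columns `class`, `tp`, `fp`, `fn`, `tn`.
#' @param rounding `"integer"`, `"one_decimal"`, or `"none"`.
#' @return Tibble with columns `class`, `precision`, `sensitivity`,
#'   `specificity`, `f1`.
#' @export
per_class_metrics <- function(counts,
                              rounding = c("integer", "one_decimal", "none")) {
  rounding <- match.arg(rounding)
  safe_pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  p <- safe_pct(counts$tp, counts$tp + counts$fp)
  s <- safe_pct(counts$tp, counts$tp + counts$fn)
  sp <- safe_pct(counts$tn, counts$tn + counts$fp)
  f1 <- ifelse(!is.na(p) & !is.na(s) & (p + s) > 0, 2 * p * s / (p + s),
               NA_real_)
  out <- tibble(class = counts$class,
                precision = apply_rounding(p, rounding),
                sensitivity = apply_rounding(s, rounding),
                specificity = apply_rounding(sp, rounding),
                f1 = apply_rounding(f1, rounding))
  attr(out, "undefined") <- counts$class[is.na(p) | is.na(s) | is.na(sp)]
  out
}

#' Overall accuracy in percent
#'
#' Either from label vectors (fraction of exact matches) or from a
#' [confusion_counts()] table (sum of per-class TP over the total). When the
#' counts table is internally inconsistent — published tables sometimes are —
#' an explicit `total` can be supplied.
#'
#' @param truth,estimate Label vectors, or pass `counts`.
#' @param counts Optional confusion-counts data frame (columns `tp`, `fn`).
#' @param total Evaluated sample count; defaults to `length(truth)` or
#'   `sum(tp) + sum(fn)`.
#' @param rounding `"integer"`, `"one_decimal"`, or `"none"`.
#' @return A single percentage.
#' @export
overall_accuracy <- function(truth = NULL, estimate = NULL, counts = NULL,
                             total = NULL,
                             rounding = c("none", "integer", "one_decimal")) {
  rounding <- match.arg(rounding)
  if (!is.null(counts)) {
    correct <- sum(counts$tp)
    total <- total %||% (sum(counts$tp) + sum(counts$fn))
  } else {
    if (length(truth) == 0) abort("need at least one sample")
    correct <- sum(as.character(truth) == as.character(estimate))
    total <- total %||% length(truth)
  }
  apply_rounding(100 * correct / total, rounding)
}

#' One-vs-rest ROC AUC per class
#'
#' For each class, scores are that class's predicted probabilities, positives
#' are the samples whose true label is the class, and the AUC is the area
#' under the ROC curve by trapezoidal integration over all score thresholds
#' (equivalently the midpoint-tie rank statistic). A class with no positives
#' (or no negatives) gets `NA`.
#'
#' @param truth True class labels.
#' @param probs Numeric matrix of class probabilities, one column per class
#'   (columns named by class or aligned with `class_order`); rows must sum to
#'   1 within `1e-6`.
#' @param class_order Optional class ordering matching the columns.
#' @return Tibble with columns `class`, `auc`, `n_pos`.
#' @export
roc_auc_ovr <- function(truth, probs, class_order = NULL) {
  probs <- as.matrix(probs)
  class_order <- class_order %||% colnames(probs) %||%
    sort(unique(as.character(truth)))
  if (ncol(probs) != length(class_order)) {
    abort("`probs` must have one column per class")
  }
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6)) abort("probability rows must sum to 1")
  truth <- as.character(truth)
  rows <- map(seq_along(class_order), function(j) {
    pos <- truth == class_order[j]
    n_pos <- sum(pos); n_neg <- sum(!pos)
    auc <- if (n_pos == 0 || n_neg == 0) NA_real_ else {
      trapezoid_auc(probs[, j], pos)
    }
    tibble(class = class_order[j], auc = auc, n_pos = n_pos)
  })
  bind_rows(rows)
}

# Area under the ROC curve: sweep thresholds from high to low over the unique
# scores, accumulate (FPR, TPR) points, integrate by trapezoids. Tied scores
# enter as a single step, which is exactly the midpoint tie convention of the
# rank statistic.
trapezoid_auc <- function(scores, pos) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp_last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[grp_last]
  fp <- cumsum(!p)[grp_last]
  tpr <- c(0, tp / sum(pos))
  fpr <- c(0, fp / sum(!pos))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Build a full evaluation report
#'
#' Bundles the confusion matrix, per-class metrics, overall accuracy and
#' (when probabilities are given) one-vs-rest AUC into one object with
#' `tidy()`, `glance()` and `autoplot()` methods.
#'
#' @param truth,estimate Label vectors.
#' @param probs Optional probability matrix for AUC.
#' @param class_order Optional class ordering.
#' @param rounding Passed to [per_class_metrics()].
#' @return An `evaluation_report`.
#' @export
evaluation_report <- function(truth, estimate, probs = NULL,
                              class_order = NULL, rounding = "integer") {
  counts <- confusion_counts(truth, estimate, class_order)
  metrics <- per_class_metrics(counts, rounding)
  auc <- if (!is.null(probs)) roc_auc_ovr(truth, probs, counts$class) else NULL
  structure(list(counts = counts, metrics = metrics,
                 accuracy = overall_accuracy(truth, estimate),
                 auc = auc, n = length(truth),
                 confusion = attr(counts, "matrix")),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", x$n, "samples |",
      nrow(x$counts), "classes | accuracy",
      sprintf("%.1f%%\n", x$accuracy))
  print(x$metrics, n = nrow(x$metrics))
  invisible(x)
}

#' @export
tidy.evaluation_report <- function(x, ...) {
  out <- left_join(x$counts, x$metrics, by = "class")
  if (!is.null(x$auc)) out <- left_join(out, x$auc[, c("class", "auc")],
                                        by = "class")
  out
}

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(n = x$n, n_classes = nrow(x$counts), accuracy = x$accuracy,
         macro_f1 = mean(x$metrics$f1, na.rm = TRUE),
         mean_auc = if (is.null(x$auc)) NA_real_ else mean(x$auc$auc,
                                                           na.rm = TRUE))
}

#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$metrics,
                            c("precision", "sensitivity", "specificity", "f1"),
                            names_to = "metric", values_to = "percent")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$percent,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "percent",
                  title = sprintf("Per-class metrics (accuracy %.1f%%)",
                                  object$accuracy)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
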