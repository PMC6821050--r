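as_logical_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  as_binary_labels(labels)$y > 0
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic normalized by n_pos * n_neg
#' (midrank convention: tied scores contribute 1/2), which equals the
#' trapezoidal area under the ROC curve.
#'
#' @param scores Numeric prediction scores (higher = more likely positive).
#' @param labels Binary labels (logical, 0/1, or "positive"/"negative").
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- as_logical_labels(labels)
  if (length(scores) != length(y))
    stop("scores and labels differ in length", call. = FALSE)
  np <- sum(y); nn <- sum(!y)
  if (np == 0 || nn == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)                        # midranks handle ties
  (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
}

# per-threshold confusion counts, thresholds descending, tied scores grouped
threshold_counts <- function(scores, labels) {
  y <- as_logical_labels(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE) # last row of each tie block
  list(tp = tp[last], fp = fp[last], n_pos = sum(y), n_neg = sum(!y))
}

#' Area under the precision-recall curve
#'
#' Step-wise area: precision is carried across each recall increment without
#' linear interpolation between PR points (linear PR interpolation overstates
#' the area). Tied scores are treated as a single threshold.
#'
#' @inheritParams auroc
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(scores, labels) {
  tc <- threshold_counts(scores, labels)
  if (tc$n_pos == 0 || tc$n_neg == 0)
    stop("both classes must be present", call. = FALSE)
  recall <- tc$tp / tc$n_pos
  precision <- tc$tp / (tc$tp + tc$fp)
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate prediction scores against labels
#'
#' Bundles AUROC, AUPR and the underlying ROC / PR curve points.
#'
#' @inheritParams auroc
#' @param protocol Tag recorded in the result (e.g. "self_test",
#'   "cross_sample").
#' @return Object of class `eg_eval`: list with `auroc`, `aupr`, `roc_points`
#'   (FPR/TPR), `pr_points` (recall/precision), `n_pos`, `n_neg`, `protocol`.
#' @export
evaluate_scores <- function(scores, labels, protocol = "scores") {
  tc <- threshold_counts(scores, labels)
  if (tc$n_pos == 0 || tc$n_neg == 0)
    stop("both classes must be present", call. = FALSE)
  roc <- data.frame(fpr = c(0, tc$fp / tc$n_neg),
                    tpr = c(0, tc$tp / tc$n_pos))
  pr <- data.frame(recall = tc$tp / tc$n_pos,
                   precision = tc$tp / (tc$tp + tc$fp))
  structure(list(auroc = auroc(scores, labels),
                 aupr = aupr(scores, labels),
                 roc_points = roc, pr_points = pr,
                 n_pos = tc$n_pos, n_neg = tc$n_neg,
                 protocol = protocol),
            class = "eg_eval")
}

#' @export
print.eg_eval <- function(x, ...) {
  cat(sprintf("%s evaluation: AUROC %.4f, AUPR %.4f (%d positives, %d negatives)\n",
              x$protocol, x$auroc, x$aupr, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.eg_eval <- function(x, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    graphics::plot(x$roc_points$fpr, x$roc_points$tpr, type = "l",
                   xlab = "false positive rate", ylab = "true positive rate",
                   main = sprintf("ROC (AUROC %.3f)", x$auroc), ...)
    graphics::abline(0, 1, lty = 3)
  } else {
    graphics::plot(x$pr_points$recall, x$pr_points$precision, type = "s",
                   xlab = "recall", ylab = "precision", ylim = c(0, 1),
                   main = sprintf("PR (AUPR %.3f)", x$aupr), ...)
    graphics::abline(h = x$n_pos / (x$n_pos + x$n_neg), lty = 3)
  }
  invisible(x)
}

check_feature_table <- function(features, feature_cols) {
  miss <- setdiff(c(feature_cols, "label"), colnames(features))
  if (length(miss))
    stop(sprintf("feature table missing column(s): %s",
                 paste(miss, collapse = ",")), call. = FALSE)
  invisible(TRUE)
}

# Balanced training subset: every positive plus an equal-sized seeded random
# sample of negatives (callers pass the half/sample they want to train on).
balanced_subset <- function(features, seed) {
  pidx <- which(features$label == "positive")
  nidx <- which(features$label == "negative")
  if (length(nidx) < length(pidx))
    stop("fewer negatives than positives; cannot balance", call. = FALSE)
  rs <- local_rng(seed)
  on.exit(rs(), add = TRUE)
  features[sort(c(pidx, sample(nidx, length(pidx)))), , drop = FALSE]
}

fit_on_features <- function(features, feature_cols, ...) {
  eg_boost.default(features[, feature_cols, drop = FALSE],
                   features$label, ...)
}

#' Self-test protocol: half for training, half for testing
#'
#' The labeled table is split in half at random, stratified by label so both
#' halves keep both classes. The model is trained on the training half — by
#' default on its balanced subsample (all positives of that half plus an equal
#' number of its negatives, mirroring the balanced training design) — and
#' every pair of the other half is scored and evaluated.
#'
#' @param features Labeled feature table (the six [EG_FEATURES] plus `label`).
#' @param seed Integer seed controlling the split and balancing.
#' @param balance Balance the training half before fitting (default TRUE).
#' @param feature_cols Feature columns to use (default the canonical six).
#' @param ... Passed to [eg_boost()] (n_trees, max_depth, ...).
#' @return An `eg_eval` with the fitted model attached as `$model`.
#' @export
self_test <- function(features, seed = 1L, balance = TRUE,
                      feature_cols = EG_FEATURES, ...) {
  check_feature_table(features, feature_cols)
  idx <- stratified_half(features$label, seed)
  train <- features[idx, , drop = FALSE]
  test <- features[-idx, , drop = FALSE]
  if (!all(c("positive", "negative") %in% train$label) ||
      !all(c("positive", "negative") %in% test$label))
    stop("too few examples to split with both classes on both sides",
         call. = FALSE)
  if (balance) train <- balanced_subset(train, seed)
  model <- fit_on_features(train, feature_cols, seed = seed, ...)
  res <- evaluate_scores(predict(model, test[, feature_cols, drop = FALSE]),
                         test$label, protocol = "self_test")
  res$model <- model
  res$seed <- seed
  res
}

stratified_half <- function(labels, seed) {
  rs <- local_rng(seed)
  on.exit(rs(), add = TRUE)
  idx <- unlist(lapply(split(seq_along(labels), labels), function(i) {
    sample(i, floor(length(i) / 2))
  }), use.names = FALSE)
  sort(idx)
}

#' Cross-sample protocol: train on one sample, test on another
#'
#' Trains on the balanced sample of the training dataset (all positives plus
#' an equal seeded draw of negatives) and scores every labeled pair of the
#' test dataset, e.g. a model built in one cell line applied to another.
#'
#' @param train_features,test_features Labeled feature tables sharing the
#'   same feature columns.
#' @param seed Integer seed for the balanced negative draw.
#' @param feature_cols Feature columns (default the canonical six).
#' @param ... Passed to [eg_boost()].
#' @return An `eg_eval` (protocol "cross_sample") with `$model` attached.
#' @export
cross_sample_test <- function(train_features, test_features, seed = 1L,
                              feature_cols = EG_FEATURES, ...) {
  check_feature_table(train_features, feature_cols)
  check_feature_table(test_features, feature_cols)
  train <- balanced_subset(train_features, seed)
  model <- fit_on_features(train, feature_cols, seed = seed, ...)
  res <- evaluate_scores(predict(model, test_features[, feature_cols, drop = FALSE]),
                         test_features$label, protocol = "cross_sample")
  res$model <- model
  res$seed <- seed
  res
}

#' Cumulative feature-ablation evaluation
#'
#' Trains and evaluates on nested feature subsets of growing size, adding the
#' features in the order EGC, GS, EWS, GWS, WEEC, DIS, using one fixed
#' stratified half-split for all subsets so the curves are comparable.
#'
#' @param features Labeled feature table.
#' @param seed Integer seed (split, balancing).
#' @param order Feature-addition order.
#' @param ... Passed to [eg_boost()].
#' @return List of `eg_eval` objects, one per subset size 1..length(order),
#'   each carrying `$features_used`.
#' @export
feature_ablation <- function(features, seed = 1L,
                             order = c("egc", "gs", "ews", "gws", "weec", "dis"),
                             ...) {
  check_feature_table(features, order)
  idx <- stratified_half(features$label, seed)
  train <- balanced_subset(features[idx, , drop = FALSE], seed)
  test <- features[-idx, , drop = FALSE]
  lapply(seq_along(order), function(k) {
    cols <- order[seq_len(k)]
    model <- fit_on_features(train, cols, seed = seed, ...)
    res <- evaluate_scores(predict(model, test[, cols, drop = FALSE]),
                           test$label, protocol = "ablation")
    res$features_used <- cols
    res
  })
}
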