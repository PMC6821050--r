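#' Boosted decision-tree classifier for enhancer-gene pairs
#'
#' Discrete AdaBoost over depth-limited `rpart` classification trees. Each
#' round fits a weak tree under the current case weights, receives a stage
#' weight `alpha = lr/2 * log((1-err)/err)`, and the weights of misclassified
#' pairs are increased (correctly classified ones decreased) before the next
#' round — weak classifiers are combined into a strong one by reweighting the
#' samples. The ensemble margin is mapped to a confidence score in \[0, 1\] by
#' a logistic transform.
#'
#' The default configuration is 50 boosting rounds of depth-3 trees; both
#' knobs are exposed (`n_trees`, `max_depth`), as is the shrinkage
#' `learning_rate`.
#'
#' @param x Numeric matrix or data.frame of feature columns (for the standard
#'   pipeline, the six [EG_FEATURES] in canonical order), or a formula.
#' @param ... Passed on to methods.
#' @return Object of class `eg_boost` with elements `trees`, `alphas`,
#'   `feature_order`, `positive_level`, `stage_error` (weighted error per
#'   round), `train_error` (ensemble training error per round) and
#'   `training_meta` (seed and class counts).
#' @export
eg_boost <- function(x, ...) UseMethod("eg_boost")

#' @rdname eg_boost
#' @param formula Model formula, e.g. `label ~ .`.
#' @param data data.frame holding the response and features.
#' @export
eg_boost.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- mf[, -1, drop = FALSE]
  fit <- eg_boost.default(x, y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname eg_boost
#' @param y Binary labels: logical, 0/1, or a two-level factor/character
#'   ("positive" is taken as the positive class when present, otherwise the
#'   second factor level).
#' @param n_trees Number of boosting rounds (weak trees), default 50.
#' @param max_depth Maximum depth of each weak tree, default 3.
#' @param learning_rate Shrinkage on the stage weights, default 1.
#' @param seed Optional integer seed recorded with the model (the fit itself
#'   is deterministic).
#' @export
eg_boost.default <- function(x, y, n_trees = 50, max_depth = 3,
                             learning_rate = 1, seed = NULL, ...) {
  x <- as.data.frame(x)
  if (!nrow(x)) stop("empty training set", call. = FALSE)
  if (anyNA(x)) stop("missing feature values in training set", call. = FALSE)
  lab <- as_binary_labels(y)
  if (length(unique(lab$y)) < 2)
    stop("training labels contain a single class", call. = FALSE)
  if (min(table(lab$y)) < 2)
    stop("need at least 2 examples per class", call. = FALSE)
  n <- nrow(x)
  w <- rep(1 / n, n)
  yf <- factor(ifelse(lab$y > 0, "pos", "neg"), levels = c("neg", "pos"))
  df <- data.frame(x, .y = yf, check.names = FALSE)
  # weak learners stay weak: rpart's standard minsplit/minbucket keep a
  # depth-limited tree from memorizing the training set, so boosting has
  # residual error to redistribute across rounds; on very small sets the
  # minimums shrink so a split remains possible at all
  minsplit <- min(20L, max(4L, floor(n / 5)))
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0,
                               minsplit = minsplit,
                               minbucket = max(2L, floor(minsplit / 3)),
                               xval = 0, maxsurrogate = 0, maxcompete = 0)
  trees <- list(); alphas <- numeric(0)
  stage_err <- train_err <- numeric(0)
  margin <- rep(0, n)
  for (t in seq_len(n_trees)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w * n, method = "class",
                        control = ctrl)
    h <- ifelse(predict(fit, df, type = "class") == "pos", 1, -1)
    err <- sum(w[h != lab$y])
    if (err >= 0.5) break                  # weak learner no better than chance
    err_c <- max(err, 1e-10)
    alpha <- learning_rate * 0.5 * log((1 - err_c) / err_c)
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    stage_err <- c(stage_err, err)
    margin <- margin + alpha * h
    train_err <- c(train_err, mean(sign(margin) != lab$y))
    if (err <= 0) break                    # perfectly separated; margin fixed
    w <- w * exp(-alpha * lab$y * h)
    w <- w / sum(w)
  }
  if (!length(trees))
    stop("boosting found no weak learner better than chance", call. = FALSE)
  structure(list(trees = trees, alphas = alphas,
                 feature_order = colnames(x),
                 positive_level = lab$positive_level,
                 stage_error = stage_err, train_error = train_err,
                 n_trees = length(trees), max_depth = max_depth,
                 learning_rate = learning_rate,
                 training_meta = list(seed = seed,
                                      n_pos = sum(lab$y > 0),
                                      n_neg = sum(lab$y < 0)),
                 call = match.call()),
            class = "eg_boost")
}

# normalize assorted binary label encodings to {-1, +1}
as_binary_labels <- function(y) {
  if (is.logical(y))
    return(list(y = ifelse(y, 1, -1), positive_level = "TRUE"))
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1)))
      stop("numeric labels must be 0/1", call. = FALSE)
    return(list(y = ifelse(y > 0, 1, -1), positive_level = "1"))
  }
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) > 2) stop("more than two label classes", call. = FALSE)
  pos <- if ("positive" %in% lev) "positive" else lev[length(lev)]
  list(y = ifelse(y == pos, 1, -1), positive_level = pos)
}

#' Predict interaction confidence from a boosted ensemble
#'
#' @param object An `eg_boost` model.
#' @param newdata Matrix or data.frame containing the model's feature columns
#'   (matched by name; extra columns are ignored). A bare matrix without
#'   column names must have exactly the model's feature count.
#' @param type "prob" (default): logistic transform of the ensemble margin
#'   into \[0,1\]; "margin": the raw weighted vote sum; "class": thresholded
#'   at probability 0.5.
#' @param ... Unused.
#' @return Numeric vector (or character vector for type = "class").
#' @export
predict.eg_boost <- function(object, newdata,
                             type = c("prob", "margin", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  if (is.null(colnames(newdata)) || !all(object$feature_order %in% colnames(newdata))) {
    if (ncol(newdata) != length(object$feature_order))
      stop(sprintf("expected %d feature column(s): %s",
                   length(object$feature_order),
                   paste(object$feature_order, collapse = ",")), call. = FALSE)
    colnames(newdata) <- object$feature_order
  }
  newdata <- newdata[, object$feature_order, drop = FALSE]
  if (anyNA(newdata)) stop("missing feature values", call. = FALSE)
  margin <- rep(0, nrow(newdata))
  for (t in seq_along(object$trees)) {
    h <- ifelse(predict(object$trees[[t]], newdata, type = "class") == "pos",
                1, -1)
    margin <- margin + object$alphas[t] * h
  }
  switch(type,
         margin = margin,
         prob = 1 / (1 + exp(-2 * margin / max(sum(object$alphas), 1e-12))),
         class = ifelse(margin > 0, object$positive_level, "negative"))
}

#' @export
print.eg_boost <- function(x, ...) {
  cat(sprintf("boosted enhancer-gene classifier: %d trees (depth <= %d), lr %.2f\n",
              x$n_trees, x$max_depth, x$learning_rate))
  cat(sprintf("  trained on %d positives / %d negatives; final training error %.4f\n",
              x$training_meta$n_pos, x$training_meta$n_neg,
              utils::tail(x$train_error, 1)))
  invisible(x)
}

#' @export
summary.eg_boost <- function(object, ...) {
  used <- table(unlist(lapply(object$trees, function(tr) {
    fr <- tr$frame$var
    as.character(fr[fr != "<leaf>"])
  })))
  structure(list(model = object, splits_per_feature = used),
            class = "summary.eg_boost")
}

#' @export
print.summary.eg_boost <- function(x, ...) {
  print(x$model)
  cat(sprintf("  stage weights: min %.3f / median %.3f / max %.3f\n",
              min(x$model$alphas), stats::median(x$model$alphas),
              max(x$model$alphas)))
  cat("  split counts per feature across the ensemble:\n")
  u <- sort(x$splits_per_feature, decreasing = TRUE)
  for (f in names(u)) cat(sprintf("    %-6s %d\n", f, u[[f]]))
  invisible(x)
}

#' @export
plot.eg_boost <- function(x, ...) {
  graphics::plot(seq_along(x$train_error), x$train_error, type = "l",
                 xlab = "boosting round", ylab = "error",
                 main = "training error by boosting round",
                 ylim = range(c(x$train_error, x$stage_error)), ...)
  graphics::lines(seq_along(x$stage_error), x$stage_error, lty = 2)
  graphics::legend("topright", c("ensemble training error", "weighted stage error"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Serialize / restore a trained model
#'
#' Single-file versioned format with the feature order embedded, so a model
#' can be trained once and applied to other samples.
#'
#' @param model An `eg_boost` model.
#' @param path File path.
#' @return `read_eg_model` returns the model; both return invisibly otherwise.
#' @export
write_eg_model <- function(model, path) {
  stopifnot(inherits(model, "eg_boost"))
  saveRDS(list(format = "eg_boost_model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname write_eg_model
#' @export
read_eg_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "eg_boost_model"))
    stop("not an eg_boost model file", call. = FALSE)
  if (!identical(obj$version, 1L))
    stop(sprintf("unsupported model file version %s", obj$version), call. = FALSE)
  obj$model
}

#' Permutation feature importance on held-out pairs
#'
#' For each feature, the importance is the mean decrease in held-out AUROC
#' over `k` random permutations of that feature's column (out-of-sample
#' permutation semantics: the examples must not be the training set). Negative
#' mean decreases are clipped to 0. Alongside the raw AUROC drop, the
#' normalized relative importance (each clipped drop divided by their sum) is
#' reported; the relative scale is the one comparable across datasets and
#' models.
#'
#' @param model An `eg_boost` model.
#' @param x Held-out feature data (matrix or data.frame).
#' @param y Held-out labels.
#' @param k Permutations per feature (default 10).
#' @param seed Integer seed for the permutations.
#' @return Object of class `eg_importance`: data.frame with columns `feature`,
#'   `drop` (mean AUROC decrease, clipped at 0) and `relative`.
#' @export
permutation_importance <- function(model, x, y, k = 10, seed = 1L) {
  x <- as.data.frame(x)[, model$feature_order, drop = FALSE]
  lab <- as_binary_labels(y)$y > 0
  base <- auroc(predict(model, x), lab)
  rs <- local_rng(seed)
  on.exit(rs(), add = TRUE)
  drops <- vapply(model$feature_order, function(f) {
    mean(vapply(seq_len(k), function(i) {
      xp <- x
      xp[[f]] <- xp[[f]][sample.int(nrow(xp))]
      base - auroc(predict(model, xp), lab)
    }, numeric(1)))
  }, numeric(1))
  clipped <- pmax(drops, 0)
  total <- sum(clipped)
  out <- data.frame(feature = model$feature_order, drop = clipped,
                    relative = if (total > 0) clipped / total else clipped * 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "baseline_auroc") <- base
  attr(out, "k") <- k
  class(out) <- c("eg_importance", "data.frame")
  out
}

#' @export
print.eg_importance <- function(x, ...) {
  cat(sprintf("permutation importance (k = %d, baseline AUROC %.4f)\n",
              attr(x, "k"), attr(x, "baseline_auroc")))
  print.data.frame(cbind(x["feature"],
                         drop = round(x$drop, 4),
                         relative = round(x$relative, 4)))
  invisible(x)
}

#' @export
plot.eg_importance <- function(x, ...) {
  graphics::barplot(x$relative, names.arg = x$feature,
                    ylab = "relative importance",
                    main = "permutation feature importance", ...)
  invisible(x)
}
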