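# Decision-tree classification of the detection groups with SMOTE
# oversampling inside training folds and nested cross-validation.

#' Confusion-matrix rates
#'
#' Accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`
#' and precision `TP/(TP+FP)`. A rate whose denominator is zero is reported
#' as missing, not 0. Values are kept at full precision; the print method
#' rounds to two decimals for display.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return A `classification_metrics` list with the four rates.
#' @examples
#' metrics_from_counts(30, 5, 39, 7)
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  tp <- unname(tp); fp <- unname(fp); tn <- unname(tn); fn <- unname(fn)
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(
    list(accuracy = rate(tp + tn, tp + fp + tn + fn),
         sensitivity = rate(tp, tp + fn),
         specificity = rate(tn, tn + fp),
         precision = rate(tp, tp + fp),
         counts = counts),
    class = "classification_metrics"
  )
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$counts["tp"], x$counts["fp"],
              x$counts["tn"], x$counts["fn"]))
  for (nm in c("accuracy", "sensitivity", "specificity", "precision")) {
    cat(sprintf("  %-11s %s\n", nm,
                ifelse(is.na(x[[nm]]), "NA", sprintf("%.2f", x[[nm]]))))
  }
  invisible(x)
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a two-class training set by interpolating new minority-class
#' points: each synthetic point lies uniformly at random on the segment
#' between a minority sample and one of its `k` nearest minority neighbours.
#' When the minority class has `m <= k` members, `k` is reduced to `m - 1`;
#' a singleton minority class is replicated.
#'
#' @param x Numeric matrix or data frame of features.
#' @param y Two-level factor of class labels.
#' @param k Number of neighbours.
#' @return List with balanced `x` (data frame) and `y` (factor).
#' @export
smote_balance <- function(x, y, k = 5) {
  x <- as.data.frame(x)
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(y) != 2) stop("SMOTE here expects exactly two classes")
  tab <- table(y)
  # single-class or already balanced input passes through untouched
  if (tab[1] == tab[2] || any(tab == 0)) return(list(x = x, y = y))
  minority <- names(tab)[which.min(tab)]
  need <- abs(diff(tab))
  min_idx <- which(y == minority)
  m <- length(min_idx)
  xm <- as.matrix(x[min_idx, , drop = FALSE])
  if (m == 1) {
    new_x <- xm[rep(1, need), , drop = FALSE]
  } else {
    kk <- min(k, m - 1)
    d <- as.matrix(dist(xm))
    diag(d) <- Inf
    nn <- apply(d, 1, function(r) order(r)[seq_len(kk)])
    nn <- matrix(nn, nrow = kk)
    base <- sample.int(m, need, replace = TRUE)
    pick <- nn[cbind(sample.int(kk, need, replace = TRUE), base)]
    u <- runif(need)
    new_x <- xm[base, , drop = FALSE] +
      u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  }
  new_x <- as.data.frame(new_x)
  names(new_x) <- names(x)
  list(x = rbind(x, new_x),
       y = factor(c(as.character(y), rep(minority, need)), levels = levels(y)))
}

#' Default decision-tree hyperparameter grid
#'
#' Maximum depth, minimum samples to split an internal node, and minimum
#' samples per leaf. `maxdepth = 30` is rpart's "unlimited" depth.
#' @return A data frame of grid points.
#' @export
default_tree_grid <- function() {
  expand.grid(maxdepth = c(2, 3, 4, 5, 30), minsplit = c(2, 4, 8),
              minbucket = c(1, 2, 4))
}

fit_tree <- function(x, y, params) {
  if (length(unique(y)) < 2) {
    # a fold can be single-class under heavy imbalance; rpart cannot fit
    # a factor with an empty level, so predict the one class seen
    return(structure(list(constant = as.character(y[1])),
                     class = "tl_constant_classifier"))
  }
  d <- cbind(x, .label = y)
  rpart::rpart(.label ~ ., data = d, method = "class",
               control = rpart::rpart.control(
                 maxdepth = params$maxdepth, minsplit = params$minsplit,
                 minbucket = params$minbucket, cp = 0, xval = 0))
}

predict_tree <- function(fit, x) {
  x <- as.data.frame(x)
  if (inherits(fit, "tl_constant_classifier")) {
    return(rep(fit$constant, nrow(x)))
  }
  as.character(predict(fit, newdata = x, type = "class"))
}

confusion_counts <- function(truth, pred, positive = "detected") {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fn <- sum(truth == positive & pred != positive)
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

score_counts <- function(cc, score) {
  m <- metrics_from_counts(cc["tp"], cc["fp"], cc["tn"], cc["fn"])
  if (score == "balanced_accuracy") {
    mean(c(m$sensitivity, m$specificity), na.rm = TRUE)
  } else {
    m$accuracy
  }
}

all_subsets <- function(cols) {
  unlist(lapply(seq_along(cols), function(sz) {
    asplit(utils::combn(cols, sz), 2)
  }), recursive = FALSE)
}

#' Train and evaluate the CFFT-range classifier
#'
#' Nested, stratified cross-validation of decision-tree classifiers on the
#' feature matrix. Outer folds provide untouched test sets; within each
#' outer training fold, SMOTE balances the classes and an inner
#' cross-validation selects the feature-family combination and the tree
#' hyperparameters (max depth, min samples to split, min samples per leaf)
#' by balanced accuracy. SMOTE is applied strictly inside (inner and outer)
#' training folds, never to validation or test folds. Confusion counts are
#' pooled over the outer test folds, so they sum to the number of
#' participants.
#'
#' @param features A `feature_matrix` from [assemble_features()].
#' @param seed Integer seed; with it fixed the report is reproducible.
#' @param outer_folds,inner_folds Numbers of CV folds.
#' @param grid Hyperparameter grid, see [default_tree_grid()].
#' @param subset_search Search all non-empty feature-family subsets
#'   (`TRUE`, default) or use all columns as-is.
#' @param smote_k SMOTE neighbour count.
#' @param score Inner-CV model-selection score: `"balanced_accuracy"`
#'   (default, the classes are imbalanced) or `"accuracy"`.
#' @return An `eval_report`: pooled counts `tp`, `fp`, `tn`, `fn`, the four
#'   rates, per-fold breakdown, and the selected features/hyperparameters
#'   per fold.
#' @export
train_eval <- function(features, seed = 1, outer_folds = 5, inner_folds = 5,
                       grid = default_tree_grid(), subset_search = TRUE,
                       smote_k = 5,
                       score = c("balanced_accuracy", "accuracy")) {
  score <- match.arg(score)
  stopifnot(inherits(features, "feature_matrix"))
  feat_cols <- setdiff(names(features), c("participant_id", "label"))
  x <- features[, feat_cols, drop = FALSE]
  y <- features$label
  if (any(table(y) < 2)) stop("need at least 2 participants per class")
  if (!is.null(seed)) set.seed(seed)
  subsets <- if (subset_search) all_subsets(feat_cols) else list(feat_cols)
  outer <- stratified_folds(y, outer_folds)
  pooled <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  folds <- list()
  for (of in seq_len(outer_folds)) {
    test <- outer == of
    if (length(unique(y[test])) < 1 || all(test) || !any(test)) next
    x_tr <- x[!test, , drop = FALSE]
    y_tr <- y[!test]
    inner <- stratified_folds(y_tr, inner_folds)
    best <- NULL
    for (sub in subsets) {
      for (g in seq_len(nrow(grid))) {
        cc <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
        for (inf in seq_len(inner_folds)) {
          val <- inner == inf
          if (!any(val) || all(val)) next
          bal <- smote_balance(x_tr[!val, sub, drop = FALSE], y_tr[!val],
                               k = smote_k)
          fit <- fit_tree(bal$x, bal$y, grid[g, ])
          pred <- predict_tree(fit, x_tr[val, sub, drop = FALSE])
          cc <- cc + confusion_counts(y_tr[val], pred)
        }
        sc <- score_counts(cc, score)
        if (is.null(best) || (is.finite(sc) && sc > best$score)) {
          best <- list(score = sc, subset = sub, params = grid[g, ])
        }
      }
    }
    bal <- smote_balance(x_tr[, best$subset, drop = FALSE], y_tr, k = smote_k)
    fit <- fit_tree(bal$x, bal$y, best$params)
    pred <- predict_tree(fit, x[test, best$subset, drop = FALSE])
    cc <- confusion_counts(y[test], pred)
    pooled <- pooled + cc
    folds[[length(folds) + 1L]] <- list(
      fold = of, counts = cc, selected_features = best$subset,
      hyperparams = best$params, inner_score = best$score,
      test_class_ratio = as.vector(table(y[test]))
    )
  }
  metrics <- metrics_from_counts(pooled["tp"], pooled["fp"], pooled["tn"],
                                 pooled["fn"])
  structure(
    list(tp = unname(pooled["tp"]), fp = unname(pooled["fp"]),
         tn = unname(pooled["tn"]), fn = unname(pooled["fn"]),
         accuracy = metrics$accuracy, sensitivity = metrics$sensitivity,
         specificity = metrics$specificity, precision = metrics$precision,
         folds = folds, seed = seed,
         threshold_freq = attr(features, "threshold_freq"),
         n = sum(pooled), score = score),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Classifier evaluation (threshold %s Hz, %d participants, seed %s)\n",
              format(x$threshold_freq), x$n, format(x$seed)))
  cat(sprintf("  True Positives  %3d    False Positives %3d\n", x$tp, x$fp))
  cat(sprintf("  True Negatives  %3d    False Negatives %3d\n", x$tn, x$fn))
  for (nm in c("accuracy", "sensitivity", "specificity", "precision")) {
    cat(sprintf("  %-11s %s\n", nm,
                ifelse(is.na(x[[nm]]), "NA", sprintf("%.2f", x[[nm]]))))
  }
  invisible(x)
}
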