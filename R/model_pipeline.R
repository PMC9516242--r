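#' Risk prediction models
#'
#' The two random-forest risk models and their evaluation machinery:
#' bootstrap class balancing, repeated-resampling stability feature
#' selection (per repeat: balanced subsample, z-score normalisation,
#' 10-fold cross-validated forests, importance threshold 0.04, feature
#' kept when it clears the threshold in more than half the repeats),
#' 70/30 split with 10-fold CV ensemble training, and evaluation by
#' ROC/AUC, decision-curve net benefit, and sensitivity/specificity
#' across cutoffs. The disease-prediction (DP) task separates
#' non-atherosclerotic controls from patients; the disease-progression
#' (DPP) task separates low-severity (CAS) from high-severity (ASCVD)
#' patients.
#'
#' @name model_pipeline
NULL

#' Bootstrap class balancing
#'
#' Brings both classes to `target_n_per_class`: classes larger than the
#' target are subsampled without replacement; classes smaller than the
#' target are bootstrap-resampled with replacement (the route by which
#' a 13-sample control group is boosted to 25).
#'
#' @param x samples x features matrix.
#' @param labels binary labels (2-level factor or 0/1), parallel to
#'   rows of `x`.
#' @param target_n_per_class target per-class size.
#' @param seed integer seed.
#' @return list of class `"balanced_dataset"`: `x`, `labels`,
#'   `provenance` (data frame: `row`, `original`, `resampled` flag).
#' @export
balance_groups <- function(x, labels, target_n_per_class, seed = 1L) {
  x <- as.matrix(x)
  f <- as.factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly two classes")
  if (min(table(f)) == 0L) stop("both classes must be nonempty")
  set.seed(seed)
  sizes <- table(f)
  pick <- lapply(levels(f), function(l) {
    idx <- which(f == l)
    if (length(idx) >= target_n_per_class)
      sample(idx, target_n_per_class)             # subsample
    else
      sample(idx, target_n_per_class, replace = TRUE) # bootstrap
  })
  idx <- unlist(pick)
  resampled <- rep(as.vector(sizes) < target_n_per_class,
                   each = target_n_per_class)
  structure(
    list(x = x[idx, , drop = FALSE], labels = f[idx],
         provenance = data.frame(row = seq_along(idx), original = idx,
                                 resampled = resampled)),
    class = "balanced_dataset")
}

# z-score normalisation fitted on a reference matrix
.zfit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(mu = mu, sd = sdv)
}
.zapply <- function(x, z) sweep(sweep(x, 2, z$mu), 2, z$sd, `/`)

# stratified k folds; returns integer fold id per sample
make_folds <- function(labels, k = 10L) {
  f <- as.factor(labels)
  fold <- integer(length(f))
  for (l in levels(f)) {
    idx <- sample(which(f == l))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stability feature selection by repeated random forests
#'
#' Per repeat: draw a class-balanced subsample (bootstrap for the
#' minority class), z-score the features within the subsample, run a
#' k-fold cross-validated random forest (one forest per training
#' fold), and average the normalised impurity importances over folds.
#' A feature scores a count when its repeat importance exceeds
#' `importance_threshold` (default 0.04 on the sum-to-one scale);
#' features whose count exceeds `count_threshold` (default half the
#' repeats) are selected.
#'
#' @param x samples x features matrix (immune features).
#' @param labels binary labels.
#' @param n_repeats number of resampling repeats (published protocol:
#'   1000).
#' @param target_n_per_class per-class subsample size per repeat
#'   (e.g. 25 for DP, 15 for DPP); default half the total size.
#' @param importance_threshold importance cut per repeat (default
#'   0.04).
#' @param count_threshold selection requires count > this (default
#'   `n_repeats / 2`).
#' @param n_folds CV folds per repeat (default 10).
#' @param n_trees trees per fold-forest (default 100 inside the repeat
#'   loop; the repeats supply the averaging).
#' @param seed integer seed.
#' @return list of class `"stability_selection"`: `counts`,
#'   `mean_importance`, `selected` (character vector), `params`.
#' @export
stability_select <- function(x, labels, n_repeats = 1000L,
                             target_n_per_class = NULL,
                             importance_threshold = 0.04,
                             count_threshold = n_repeats / 2,
                             n_folds = 10L, n_trees = 100L, seed = 1L) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least two features")
  f <- as.factor(labels)
  if (nlevels(f) != 2L) stop("labels must be binary")
  if (is.null(target_n_per_class))
    target_n_per_class <- ceiling(length(f) / 2)
  p <- ncol(x)
  counts <- setNames(numeric(p), colnames(x))
  imp_sum <- counts
  set.seed(seed)
  for (r in seq_len(n_repeats)) {
    bal <- balance_groups(x, f, target_n_per_class,
                          seed = sample.int(2^31 - 1, 1))
    bx <- .zapply(bal$x, .zfit(bal$x))
    by <- bal$labels
    fold <- make_folds(by, n_folds)
    imp <- numeric(p)
    used <- 0L
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      if (length(unique(by[tr])) < 2L) next
      fit <- rf_fit(bx[tr, , drop = FALSE], by[tr], n_trees = n_trees)
      imp <- imp + fit$importance
      used <- used + 1L
    }
    imp <- imp / used
    counts <- counts + (imp > importance_threshold)
    imp_sum <- imp_sum + imp
  }
  structure(
    list(counts = counts, mean_importance = imp_sum / n_repeats,
         selected = names(counts)[counts > count_threshold],
         params = list(n_repeats = n_repeats,
                       target_n_per_class = target_n_per_class,
                       importance_threshold = importance_threshold,
                       count_threshold = count_threshold,
                       n_folds = n_folds, n_trees = n_trees)),
    class = "stability_selection")
}

#' @export
print.stability_selection <- function(x, ...) {
  cat("Stability selection over", x$params$n_repeats, "repeats:",
      length(x$selected), "of", length(x$counts),
      "features selected\n")
  if (length(x$selected))
    cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Train a cross-validated random-forest ensemble
#'
#' Stratified 70/30 train/test split, optional bootstrap balancing of
#' the training set (the DP protocol), z-score normalisation fitted on
#' the training set, then k-fold CV on the training set: one forest
#' per training fold, ensembled by averaging predicted probabilities.
#'
#' @param x samples x features matrix.
#' @param labels binary labels (second level = positive class).
#' @param feature_set optional character vector restricting the
#'   feature columns.
#' @param train_frac training fraction (default 0.7).
#' @param balance_train `NULL`, or a per-class target size for
#'   [balance_groups()] applied to the training set only.
#' @param n_folds CV folds (default 10).
#' @param n_trees trees per fold-model (default 500).
#' @param seed integer seed.
#' @return list of class `"trained_ensemble"`: `models`, `norm`,
#'   `features`, `levels`, `train_idx`, `test_idx`, `test_scores`,
#'   `test_labels`.
#' @export
train_ensemble <- function(x, labels, feature_set = NULL,
                           train_frac = 0.7, balance_train = NULL,
                           n_folds = 10L, n_trees = 500L, seed = 1L) {
  x <- as.matrix(x)
  f <- as.factor(labels)
  if (nlevels(f) != 2L) stop("labels must be binary")
  if (!is.null(feature_set)) x <- x[, feature_set, drop = FALSE]
  if (nrow(x) < 20L) stop("need at least 20 samples")
  set.seed(seed)
  # stratified split of original samples (before any bootstrap)
  train_idx <- unlist(lapply(levels(f), function(l) {
    idx <- which(f == l)
    sample(idx, round(train_frac * length(idx)))
  }))
  test_idx <- setdiff(seq_len(nrow(x)), train_idx)
  xtr <- x[train_idx, , drop = FALSE]; ytr <- f[train_idx]
  if (!is.null(balance_train)) {
    bal <- balance_groups(xtr, ytr, balance_train,
                          seed = sample.int(2^31 - 1, 1))
    xtr <- bal$x; ytr <- bal$labels
  }
  norm <- .zfit(xtr)
  xtr <- .zapply(xtr, norm)
  fold <- make_folds(ytr, n_folds)
  models <- lapply(seq_len(n_folds), function(k) {
    tr <- fold != k
    if (length(unique(ytr[tr])) < 2L)
      stop("fold without both classes; reduce n_folds")
    rf_fit(xtr[tr, , drop = FALSE], ytr[tr], n_trees = n_trees)
  })
  xte <- .zapply(x[test_idx, , drop = FALSE], norm)
  scores <- rowMeans(vapply(models, predict, numeric(nrow(xte)),
                            newdata = xte))
  structure(
    list(models = models, norm = norm, features = colnames(x),
         levels = levels(f), train_idx = train_idx,
         test_idx = test_idx, test_scores = scores,
         test_labels = f[test_idx]),
    class = "trained_ensemble")
}

#' @describeIn train_ensemble Ensemble prediction: mean predicted
#'   probability over fold-models.
#' @param object a `"trained_ensemble"`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @export
predict.trained_ensemble <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$features, drop = FALSE]
  newdata <- .zapply(newdata, object$norm)
  rowMeans(vapply(object$models, predict, numeric(nrow(newdata)),
                  newdata = newdata))
}

#' ROC curve and AUC
#'
#' ROC points over all score thresholds; AUC by trapezoidal
#' integration, which equals the pairwise concordance estimator
#' (probability that a random positive outranks a random negative,
#' ties counted 1/2).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (second factor level or 1 = positive).
#' @return list of class `"roc_curve"`: `points` (data frame `fpr`,
#'   `tpr`, `threshold`), `auc`.
#' @export
roc_curve <- function(scores, labels) {
  y <- .as01(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- !duplicated(ss, fromLast = TRUE) # end of each tie block
  pts <- data.frame(fpr = c(0, fp[last] / n0),
                    tpr = c(0, tp[last] / n1),
                    threshold = c(Inf, ss[last]))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

.as01 <- function(labels) {
  f <- as.factor(labels)
  if (nlevels(f) > 2L) stop("labels must be binary")
  as.integer(f == levels(f)[nlevels(f)])
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC with %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Decision curve analysis (net benefit)
#'
#' Net benefit of treating according to `score >= pt` at threshold
#' probability pt: `TP/N - (FP/N) * pt / (1 - pt)`. The treat-none
#' policy has net benefit 0 everywhere; treat-all has
#' `prevalence - (1 - prevalence) * pt / (1 - pt)`.
#'
#' @param scores prediction scores in `[0, 1]`.
#' @param labels binary labels.
#' @param thresholds vector of threshold probabilities in `(0, 1)`.
#' @return data frame: `threshold`, `net_benefit`, `all_positive`,
#'   `all_negative`.
#' @export
decision_curve <- function(scores, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)")
  y <- .as01(labels)
  n <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(pt) {
    pred <- scores >= pt
    tp <- sum(pred & y == 1L)
    fp <- sum(pred & y == 0L)
    tp / n - (fp / n) * pt / (1 - pt)
  }, numeric(1))
  data.frame(threshold = thresholds, net_benefit = nb,
             all_positive = prev - (1 - prev) * thresholds /
               (1 - thresholds),
             all_negative = 0)
}

#' Sensitivity and specificity across cutoffs
#'
#' Classifies `score >= cutoff` as positive and reports sensitivity
#' and specificity per cutoff, plus the cutoff maximising Youden's J
#' (sensitivity + specificity - 1).
#'
#' @param scores prediction scores.
#' @param labels binary labels.
#' @param cutoffs cutoff grid (default 0.05 ... 0.95).
#' @return list: `table` (data frame `cutoff`, `sensitivity`,
#'   `specificity`, `youden`), `best_cutoff`.
#' @export
cutoff_analysis <- function(scores, labels,
                            cutoffs = seq(0.05, 0.95, by = 0.05)) {
  y <- .as01(labels)
  tab <- do.call(rbind, lapply(cutoffs, function(ct) {
    pred <- scores >= ct
    data.frame(cutoff = ct,
               sensitivity = sum(pred & y == 1L) / sum(y == 1L),
               specificity = sum(!pred & y == 0L) / sum(y == 0L))
  }))
  tab$youden <- tab$sensitivity + tab$specificity - 1
  list(table = tab, best_cutoff = tab$cutoff[which.max(tab$youden)])
}
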