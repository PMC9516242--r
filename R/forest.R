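#' Fit a random forest classifier
#'
#' Bagged CART trees for binary classification: each tree is grown on a
#' bootstrap sample of the rows, considering `mtry` randomly chosen
#' features at every split and maximising the decrease in Gini impurity.
#' Variable importance is the mean decrease in impurity per feature,
#' node-weighted and averaged over trees, then normalised to sum to one
#' (so a threshold such as 0.04 is comparable across feature-set sizes).
#'
#' Implemented in compiled code against R's RNG, so results are
#' reproducible under [set.seed()].
#'
#' @param x numeric matrix of predictors (samples x features).
#' @param y binary response: a factor with two levels or a 0/1 vector.
#'   The second factor level (or 1) is the positive class.
#' @param n_trees number of trees (default 500).
#' @param mtry features considered per split; default `floor(sqrt(p))`.
#' @param min_node minimum samples in a terminal node (default 1).
#' @param max_depth maximum tree depth (default 25).
#' @return An object of class `"cad_rf"` with elements `trees`,
#'   `importance` (named, sums to 1 when any split was made),
#'   `importance_raw`, `levels`, and `feature_names`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 50, 4)
#' y <- as.integer(x[, 1] + rnorm(50, sd = 0.2) > 0)
#' fit <- rf_fit(x, y, n_trees = 50)
#' which.max(fit$importance)
#' @export
rf_fit <- function(x, y, n_trees = 500L, mtry = NULL, min_node = 1L,
                   max_depth = 25L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.factor(y)) {
    levels_y <- levels(y)
    if (length(levels_y) != 2L) stop("y must have exactly two levels")
    yy <- as.integer(y == levels_y[2L])
  } else {
    levels_y <- c("0", "1")
    yy <- as.integer(y)
    if (!all(yy %in% c(0L, 1L))) stop("y must be binary (0/1 or 2-level factor)")
  }
  if (length(yy) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (length(unique(yy)) < 2L) stop("both classes must be present")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  mtry <- min(as.integer(mtry), ncol(x))

  fit <- .rf_fit_cpp(x, yy, as.integer(n_trees), mtry,
                     as.integer(min_node), as.integer(max_depth))
  raw <- as.numeric(fit$importance)
  names(raw) <- colnames(x)
  imp <- if (sum(raw) > 0) raw / sum(raw) else raw
  structure(
    list(trees = fit$trees, importance = imp, importance_raw = raw,
         levels = levels_y, feature_names = colnames(x),
         n_trees = as.integer(n_trees), mtry = mtry),
    class = "cad_rf")
}

#' @describeIn rf_fit Predict class-1 probabilities (mean of per-tree
#'   terminal-node probabilities).
#' @param object a fitted `"cad_rf"`.
#' @param newdata matrix or data frame with the training feature columns.
#' @param ... unused.
#' @export
predict.cad_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  storage.mode(newdata) <- "double"
  .rf_predict_cpp(object$trees, newdata)
}

#' @export
print.cad_rf <- function(x, ...) {
  cat("Random forest (", x$n_trees, " trees, mtry = ", x$mtry, ", ",
      length(x$importance), " features)\n", sep = "")
  invisible(x)
}
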