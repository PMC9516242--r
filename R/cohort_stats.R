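#' Cohort-level statistics
#'
#' Group comparisons used throughout the cohort analysis: Pearson
#' chi-squared for categorical clinical variables, one-way ANOVA
#' reconstructed from printed summary statistics, BH-adjusted pairwise t
#' tests on immune feature tables, and correlation analyses against
#' clinical severity (Gensini score) and serum lipids.
#'
#' @name cohort_stats
NULL

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction is applied (the cohort tables are 3 x 2;
#' Yates' correction would not reproduce the published p values).
#'
#' @param counts integer matrix of group x category counts, at least
#'   2 x 2.
#' @return list with `statistic`, `df`, `p.value`, `expected`.
#' @examples
#' chisq_test(rbind(c(2, 11), c(15, 23), c(22, 10)))
#' @export
chisq_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least a 2x2 table")
  if (any(counts < 0)) stop("counts must be nonnegative")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("zero marginal in contingency table")
  expected <- outer(rs, cs) / sum(counts)
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' One-way ANOVA from per-group summary statistics
#'
#' Reconstructs the F test from group means, SDs and sizes: the
#' between-group sum of squares from the means, the within-group sum of
#' squares from the SDs. Identical to raw-data one-way ANOVA when the
#' summaries are exact.
#'
#' @param means,sds,ns numeric vectors, one entry per group (`ns >= 2`).
#' @return list with `F`, `df1`, `df2`, `p.value`.
#' @examples
#' # total cholesterol rows of a 3-group cohort table
#' anova_from_summary(c(5.02, 4.40, 4.22), c(0.90, 0.77, 0.96),
#'                    c(13, 38, 32))
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2L || length(sds) != k || length(ns) != k)
    stop("means, sds, ns must have equal length >= 2")
  if (any(ns < 2)) stop("each group needs n >= 2")
  if (any(sds < 0)) stop("sds must be nonnegative")
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, df1 = k - 1L, df2 = N - k,
       p.value = pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return monotone adjusted p values, capped at 1; never below the
#'   raw p values.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p values must be in [0, 1]")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

.stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", ""), right = TRUE)
}

#' Pairwise group comparisons of immune features with BH adjustment
#'
#' Unpaired two-sided Welch or pooled-variance t tests for every feature
#' and every requested group pair, with BH adjustment applied within
#' each pair's feature family (the adjustment family is configurable by
#' calling per pair). Significance stars use the conventional
#' 0.05/0.01/0.001/0.0001 thresholds on adjusted p.
#'
#' @param features samples x features numeric matrix or data frame (e.g.
#'   a frequency table).
#' @param groups factor/character of group membership per sample.
#' @param pairs list of length-2 character vectors of group levels;
#'   default all pairs.
#' @param var.equal passed to [t.test()]; default `TRUE` (classical
#'   Student's t).
#' @return data frame with columns `feature`, `group1`, `group2`, `t`,
#'   `p`, `p.adj`, `stars`. Features with degenerate variance in both
#'   groups get `p = 1` with a warning.
#' @export
group_compare <- function(features, groups, pairs = NULL,
                          var.equal = TRUE) {
  features <- as.matrix(features)
  groups <- as.character(groups)
  if (length(groups) != nrow(features))
    stop("groups must have one entry per sample (row)")
  lev <- unique(groups)
  if (is.null(pairs))
    pairs <- utils::combn(lev, 2, simplify = FALSE)
  out <- NULL
  for (pr in pairs) {
    a <- features[groups == pr[1], , drop = FALSE]
    b <- features[groups == pr[2], , drop = FALSE]
    if (nrow(a) < 2L || nrow(b) < 2L) stop("need >= 2 samples per group")
    res <- vapply(seq_len(ncol(features)), function(j) {
      xa <- a[, j]; xb <- b[, j]
      if (var(xa) == 0 && var(xb) == 0) {
        warning("degenerate variance for feature ",
                colnames(features)[j] %||% j, call. = FALSE)
        return(c(0, 1))
      }
      tt <- t.test(xa, xb, var.equal = var.equal)
      c(unname(tt$statistic), tt$p.value)
    }, numeric(2))
    block <- data.frame(
      feature = colnames(features) %||% as.character(seq_len(ncol(features))),
      group1 = pr[1], group2 = pr[2],
      t = res[1, ], p = res[2, ],
      p.adj = bh_adjust(res[2, ]),
      stringsAsFactors = FALSE)
    out <- rbind(out, block)
  }
  out$stars <- as.character(.stars(out$p.adj))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlation between an immune feature and a clinical variable
#'
#' @param x,y numeric vectors; pairs with missing values are dropped
#'   listwise.
#' @param method `"pearson"` (default, as in figure-facing outputs) or
#'   `"spearman"`.
#' @return list of class `"cad_correlation"` with `r`, `p.value`, `n`,
#'   `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(structure(list(r = NA_real_, p.value = NA_real_, n = n,
                          method = method), class = "cad_correlation"))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  structure(list(r = unname(ct$estimate), p.value = ct$p.value, n = n,
                 method = method), class = "cad_correlation")
}

#' @export
print.cad_correlation <- function(x, ...) {
  cat(sprintf("%s r = %.3f, p = %.4g (n = %d)\n", x$method, x$r,
              x$p.value, x$n))
  invisible(x)
}

#' Pairwise correlation network of immune features within one group
#'
#' Full symmetric matrix of pairwise correlations, with a significance
#' mask at unadjusted p < alpha (matching how such networks are usually
#' displayed: a marker on each significant cell). The diagonal is 1 and
#' excluded from significant-pair counts.
#'
#' @param features samples x features matrix for a single group.
#' @param method correlation method, see [correlate()].
#' @param alpha significance level for the mask (default 0.05).
#' @return list with `r` (matrix), `p` (matrix), `significant` (logical
#'   matrix, diagonal `FALSE`), `n_significant_pairs`.
#' @export
correlation_network <- function(features, method = c("pearson", "spearman"),
                                alpha = 0.05) {
  method <- match.arg(method)
  features <- as.matrix(features)
  p <- ncol(features)
  rmat <- matrix(1, p, p, dimnames = list(colnames(features),
                                          colnames(features)))
  pmat <- matrix(NA_real_, p, p, dimnames = dimnames(rmat))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (j <= i) next
    res <- correlate(features[, i], features[, j], method = method)
    rmat[i, j] <- rmat[j, i] <- res$r
    pmat[i, j] <- pmat[j, i] <- res$p.value
  }
  sig <- !is.na(pmat) & pmat < alpha
  diag(sig) <- FALSE
  list(r = rmat, p = pmat, significant = sig,
       n_significant_pairs = sum(sig[upper.tri(sig)]))
}
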