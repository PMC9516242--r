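test_that("balance_groups subsamples the majority and bootstraps the minority", {
  set.seed(70)
  x <- matrix(rnorm(83 * 3), 83, 3)
  y <- rep(c("NC", "AS"), c(13, 70))
  bal <- balance_groups(x, y, 25, seed = 4)
  expect_equal(as.vector(table(bal$labels)), c(25L, 25L))
  expect_equal(nrow(bal$x), 50L)
  # minority rows all trace back to the 13 originals, with replacement
  nc_rows <- bal$provenance$original[bal$labels == "NC"]
  expect_true(all(nc_rows %in% which(y == "NC")))
  expect_true(any(duplicated(nc_rows)))
  expect_true(all(bal$provenance$resampled[bal$labels == "NC"]))
  # majority rows are distinct originals
  as_rows <- bal$provenance$original[bal$labels == "AS"]
  expect_false(any(duplicated(as_rows)))
  expect_false(any(bal$provenance$resampled[bal$labels == "AS"]))
  # already balanced at target: a permutation of the input
  y2 <- rep(c("a", "b"), each = 25)
  bal2 <- balance_groups(x[1:50, ], y2, 25, seed = 5)
  expect_equal(sort(bal2$provenance$original), 1:50)
  # determinism
  bal3 <- balance_groups(x, y, 25, seed = 4)
  expect_identical(bal$provenance, bal3$provenance)
})

test_that("roc_curve matches closed forms and tie conventions", {
  expect_equal(roc_curve(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc, 0.75)
  expect_equal(roc_curve(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  r <- roc_curve(runif(50), rbinom(50, 1, 0.4))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_error(roc_curve(1:5, rep(1, 5)), "both classes")
})

test_that("decision curves match the closed forms", {
  y <- rep(c(1, 0), c(30, 70))
  pts <- seq(0.05, 0.95, by = 0.05)
  # all-negative model: net benefit 0 everywhere
  dc0 <- decision_curve(rep(0, 100), y, pts)
  expect_equal(dc0$net_benefit, rep(0, length(pts)))
  # treat-all line at prevalence 0.5 and pt 0.5 is 0
  dc <- decision_curve(runif(20), rep(c(0, 1), 10), 0.5)
  expect_equal(dc$all_positive, 0)
  # perfect classifier: net benefit = prevalence at every pt
  dcp <- decision_curve(y, y, pts)
  expect_equal(dcp$net_benefit, rep(0.3, length(pts)))
  expect_true(all(dcp$net_benefit <= mean(y) + 1e-12))
  expect_error(decision_curve(runif(10), rbinom(10, 1, 0.5), c(0.5, 1)),
               "\\(0, 1\\)")
})

test_that("cutoff analysis counts sensitivity/specificity and best Youden", {
  sc <- c(0.2, 0.4, 0.6, 0.8)
  y <- c(0, 0, 1, 1)
  res <- cutoff_analysis(sc, y, cutoffs = c(0, 0.5, 1))
  expect_equal(res$table$sensitivity, c(1, 1, 0))
  expect_equal(res$table$specificity, c(0, 1, 1))
  expect_equal(res$best_cutoff, 0.5)
})

test_that("stability selection obeys the counting rule on forced cases", {
  set.seed(72)
  # a feature that separates perfectly is counted in every repeat
  n <- 40
  x <- cbind(strong = c(rnorm(20, -3), rnorm(20, 3)),
             noise1 = rnorm(n), noise2 = rnorm(n))
  y <- rep(c(0, 1), each = 20)
  ss <- stability_select(x, y, n_repeats = 25, target_n_per_class = 15,
                         n_trees = 30, seed = 1)
  expect_equal(unname(ss$counts["strong"]), 25)
  expect_true("strong" %in% ss$selected)
  expect_true(all(ss$counts >= 0 & ss$counts <= 25))
  # selected <=> count > threshold
  expect_setequal(ss$selected,
                  names(ss$counts)[ss$counts > ss$params$count_threshold])
})

test_that("pure-noise stability selection keeps counts low", {
  set.seed(73)
  # Null world: 30 noise features, random labels. Per-feature counts
  # stay far below the selection threshold on average, and far fewer
  # features are selected than in any planted-signal world. (A fixed
  # small cohort retains some spuriously separating features that
  # resampling cannot wash out, so occasional null selections are
  # expected; see the methods vignette.)
  res <- lapply(1:15, function(i) {
    x <- matrix(rnorm(30 * 30), 30, 30,
                dimnames = list(NULL, paste0("f", 1:30)))
    y <- rep(c(0, 1), each = 15)
    ss <- stability_select(x, y, n_repeats = 40,
                           target_n_per_class = 12, n_trees = 25,
                           seed = 100 + i)
    c(n_sel = length(ss$selected), med = median(ss$counts),
      mean_count = mean(ss$counts))
  })
  res <- do.call(rbind, res)
  # typical feature is counted in well under half the repeats
  expect_lt(mean(res[, "med"]), 0.30 * 40)
  expect_lt(mean(res[, "mean_count"]), 0.35 * 40)
  # only a small minority of the 30 null features ever gets selected
  expect_lt(mean(res[, "n_sel"]) / 30, 0.25)
})

test_that("stability counts rise with planted effect size", {
  set.seed(74)
  count_at <- function(delta) {
    mean(vapply(1:5, function(i) {
      x <- matrix(rnorm(40 * 10), 40, 10,
                  dimnames = list(NULL, paste0("f", 1:10)))
      x[21:40, 1] <- x[21:40, 1] + delta
      ss <- stability_select(x, rep(0:1, each = 20), n_repeats = 30,
                             target_n_per_class = 15, n_trees = 25,
                             seed = 200 + i)
      unname(ss$counts["f1"])
    }, numeric(1)))
  }
  c0 <- count_at(0); c1 <- count_at(1.5); c2 <- count_at(3)
  expect_lt(c0, c2)
  expect_lte(c1, c2 + 1)   # monotone in expectation, small MC slack
})

test_that("train_ensemble separates separable data and averages fold models", {
  set.seed(75)
  x <- matrix(rnorm(60 * 4), 60, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- factor(ifelse(x[, 2] > 0, "pos", "neg"), levels = c("neg", "pos"))
  te <- train_ensemble(x, y, n_trees = 100, seed = 3)
  expect_equal(roc_curve(te$test_scores, te$test_labels)$auc, 1)
  expect_length(te$models, 10L)
  # ensemble prediction = mean of fold-model predictions
  newx <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
  manual <- rowMeans(vapply(te$models, function(m)
    predict(m, immunoCAD:::.zapply(newx, te$norm)), numeric(5)))
  expect_equal(predict(te, newx), manual)
  # train/test split is a partition of the originals
  expect_setequal(c(te$train_idx, te$test_idx), 1:60)
  expect_error(train_ensemble(x[1:10, ], y[1:10]), "20 samples")
})
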