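test_that("kNN graph matches forced geometry and the brute-force oracle", {
  # 3 points on a line, k = 1: middle point joined to nearest endpoint
  x <- matrix(c(0, 1, 10), ncol = 1)
  g <- build_knn_graph(x, k = 1)
  expect_true(igraph::are_adjacent(g, 1, 2))
  # duplicate points: zero-distance edges retained with weight 1
  gd <- build_knn_graph(matrix(c(0, 0, 5), ncol = 1), k = 1)
  expect_true(igraph::are_adjacent(gd, 1, 2))
  expect_equal(max(igraph::E(gd)$weight), 1)
  expect_error(build_knn_graph(x, k = 3), "smaller")

  # exact kNN vs brute force on 500 points at k = 15
  set.seed(40)
  y <- matrix(rnorm(500 * 4), 500, 4)
  nn <- FNN::get.knn(y, k = 15)$nn.index
  d <- as.matrix(dist(y))
  diag(d) <- Inf
  brute <- t(apply(d, 1, function(r) order(r)[1:15]))
  agree <- mean(vapply(1:500, function(i)
    length(intersect(nn[i, ], brute[i, ])) / 15, numeric(1)))
  expect_equal(agree, 1)
})

test_that("community detection recovers blob structure", {
  set.seed(41)
  # two well-separated blobs -> 2 clusters, ARI = 1
  x <- rbind(matrix(rnorm(200 * 5), 200, 5),
             matrix(rnorm(200 * 5, mean = 6), 200, 5))
  cl <- community_cluster(build_knn_graph(x, k = 15), seed = 2)
  expect_equal(length(levels(cl$label)), 2L)
  expect_equal(adjusted_rand_index(cl$label, rep(1:2, each = 200)), 1)
  # one homogeneous blob -> 1 cluster
  xb <- matrix(rnorm(300 * 10), 300, 10)
  cb <- community_cluster(build_knn_graph(xb, k = 30), seed = 2)
  expect_equal(length(levels(cb$label)), 1L)
  expect_error(community_cluster(igraph::make_empty_graph(0)), "empty")
})

test_that("clustering is stable under event-order permutation", {
  set.seed(42)
  x <- rbind(matrix(rnorm(150 * 4), 150, 4),
             matrix(rnorm(150 * 4, mean = 5), 150, 4))
  perm <- sample(nrow(x))
  c1 <- community_cluster(build_knn_graph(x, k = 10), seed = 3)
  c2 <- community_cluster(build_knn_graph(x[perm, ], k = 10), seed = 3)
  expect_equal(adjusted_rand_index(c1$label[perm], c2$label), 1)
})

test_that("annotation follows the ordered marker rules", {
  pan <- marker_panel("tcell")$marker
  mk <- function(...) {
    v <- setNames(rep(0, length(pan)), pan)
    args <- c(...)
    v[names(args)] <- args
    v
  }
  med <- rbind(
    cd4 = mk(CD45 = 4, CD3 = 4, CD4 = 4, CD127 = 4),
    cd8 = mk(CD45 = 4, CD3 = 4, CD8a = 4, CD127 = 4),
    gd = mk(CD45 = 4, CD3 = 4, TCRgd = 4),
    treg = mk(CD45 = 4, CD3 = 4, CD4 = 4, CD25 = 4),
    b = mk(CD45 = 4, CD19 = 4),
    nk = mk(CD45 = 4, CD56 = 4, CD16 = 4),
    cmon = mk(CD45 = 4, CD14 = 4, CD33 = 4, `HLA-DR` = 4),
    imon = mk(CD45 = 4, CD14 = 4, CD16 = 4, CD33 = 4, `HLA-DR` = 4),
    ncmon = mk(CD45 = 4, CD16 = 4, CD33 = 4, `HLA-DR` = 4),
    gran = mk(CD45 = 2, CD66b = 4),
    blank = mk())
  ann <- annotate_clusters(med, thresholds = setNames(rep(1, length(pan)),
                                                      pan))
  got <- setNames(ann$subset, ann$cluster)
  expect_equal(got[["cd4"]], "CD4 Tem")
  expect_equal(got[["cd8"]], "CD8 Tem")
  expect_equal(got[["gd"]], "gdT")
  expect_equal(got[["treg"]], "CD4 Treg")
  expect_equal(got[["b"]], "B")
  expect_equal(got[["nk"]], "NK")
  expect_equal(got[["cmon"]], "cMon")
  expect_equal(got[["imon"]], "iMon")
  expect_equal(got[["ncmon"]], "ncMon")
  expect_equal(got[["gran"]], "granulocyte")
  expect_equal(got[["blank"]], "unassigned")
  majors <- setNames(ann$major, ann$cluster)
  expect_equal(unname(majors[c("cd4", "b", "nk", "cmon", "gran")]),
               c("T", "B", "NK", "myeloid", "granulocyte"))
  # annotation is total
  expect_false(any(is.na(ann$major)))
  expect_error(annotate_clusters(med[, 1:3]), "missing marker")
})

test_that("generated lineages are recovered end to end", {
  d <- cohort_design(n_per_group = c(NC = 1L, CAS = 1L, ASCVD = 1L),
                     cells_per_sample = 800L, panel = "tcell",
                     seed = 44L)
  co <- generate_cohort(d)
  ev <- lapply(co$events, arcsinh_transform)
  res <- cluster_samples(ev, k = 20, seed = 5)
  ann <- annotate_clusters(res$assignment$medians)
  truth_lineage <- unlist(co$truth$labels)
  truth_lineage <- vapply(truth_lineage, function(l)
    d$cluster_profiles[[l]]$lineage, "")
  # map generator archetypes to annotation major types
  map <- c(CD4T = "T", CD8T = "T", gdT = "T", DNT = "T", B = "B",
           NK = "NK", Mono = "myeloid", Gran = "granulocyte")
  pred_major <- setNames(ann$major, ann$cluster)[res$assignment$label]
  expect_gt(mean(pred_major == map[truth_lineage]), 0.95)
})

test_that("frequency tables normalise per sample over the label space", {
  sid <- rep(c("a", "b"), c(100, 50))
  lab <- c(rep("T", 60), rep("B", 40), rep("T", 50))
  ft <- frequency_table(sid, lab)
  expect_equal(ft["a", "T"], 0.6)
  expect_equal(ft["a", "B"], 0.4)
  expect_equal(ft["b", "B"], 0)        # missing label -> 0
  expect_equal(unname(rowSums(ft)), c(1, 1))
  # extended label space keeps zero columns
  ft2 <- frequency_table(sid, lab, all_labels = c("T", "B", "NK"))
  expect_equal(ft2["a", "NK"], 0)
  expect_equal(unname(rowSums(ft2)), c(1, 1))
})

test_that("t-SNE embedding is deterministic and separates blobs", {
  set.seed(46)
  x <- rbind(matrix(rnorm(500 * 5), 500, 5),
             matrix(rnorm(500 * 5, mean = 6), 500, 5))
  e1 <- embed_tsne(x, seed = 7, perplexity = 30)
  e2 <- embed_tsne(x, seed = 7, perplexity = 30)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(1000L, 2L))
  # silhouette of the true labels in the embedding
  lab <- rep(1:2, each = 500)
  dmat <- as.matrix(dist(e1))
  sil <- vapply(seq_len(1000), function(i) {
    a <- mean(dmat[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(dmat[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  expect_error(embed_tsne(x[1:50, ], perplexity = 30), "perplexity")
})
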