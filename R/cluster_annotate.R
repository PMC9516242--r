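#' Graph-based clustering and lineage annotation
#'
#' CD45+ events from all samples are pooled, embedded in a kNN graph on
#' the arcsinh-scale marker space, partitioned by modularity community
#' detection (Leiden), optionally merged below a minimum community
#' size, and labelled back per sample. Lineages are then assigned to
#' clusters from their median marker profiles by ordered marker rules,
#' and per-sample relative frequency tables are derived.
#'
#' @name cluster_annotate
NULL

#' Build a kNN graph over events
#'
#' Exact k-nearest-neighbour search (union-kNN graph) with
#' inverse-distance edge weights and optional pruning of the weakest
#' edges. For the cosine metric, rows are L2-normalised first (which
#' preserves cosine neighbour ranking).
#'
#' @param x numeric events x markers matrix (arcsinh scale).
#' @param k neighbours per event (default 30); must be `< nrow(x)`.
#' @param metric `"euclidean"` or `"cosine"`.
#' @param prune_quantile drop edges with weight below this quantile
#'   (default 0 = keep all).
#' @return an [igraph::graph] with `weight` edge attribute.
#' @export
build_knn_graph <- function(x, k = 30L, metric = c("euclidean", "cosine"),
                            prune_quantile = 0) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of events")
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(x^2))
    x <- x / ifelse(nrm > 0, nrm, 1)
  }
  nn <- FNN::get.knn(x, k = k)
  from <- rep(seq_len(n), k)
  to <- as.vector(nn$nn.index)
  d <- as.vector(nn$nn.dist)
  # union kNN: canonical order, deduplicate, keep smallest distance
  a <- pmin(from, to); b <- pmax(from, to)
  o <- order(a, b, d)
  a <- a[o]; b <- b[o]; d <- d[o]
  dup <- duplicated(cbind(a, b))
  a <- a[!dup]; b <- b[!dup]; d <- d[!dup]
  w <- 1 / (1 + d)
  if (prune_quantile > 0) {
    keep <- w >= quantile(w, prune_quantile)
    a <- a[keep]; b <- b[keep]; w <- w[keep]
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(a, b))
  igraph::E(g)$weight <- w
  g
}

#' Community clustering of a kNN graph
#'
#' Leiden modularity optimisation on the weighted graph, followed by
#' merging of communities smaller than a minimum size into their most
#' connected neighbour community. Cluster labels are deterministic
#' given the seed and ordered by size (C01 = largest).
#'
#' @param graph graph from [build_knn_graph()].
#' @param resolution Leiden resolution parameter (default 0.3; on
#'   inverse-distance-weighted kNN graphs this recovers well-separated
#'   mixture components without shattering homogeneous point clouds).
#' @param seed integer seed (community detection is stochastic).
#' @param min_size_frac minimum community size as a fraction of events
#'   (default 0.001).
#' @param x optional events matrix used for median profiles.
#' @return list of class `"cluster_assignment"`: `label` (factor per
#'   event), `sizes`, and `medians` (clusters x markers, when `x`
#'   given).
#' @export
community_cluster <- function(graph, resolution = 0.3, seed = 1L,
                              min_size_frac = 0.001, x = NULL) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  memb <- withr_seed(seed, {
    igraph::membership(igraph::cluster_leiden(
      graph, objective_function = "modularity",
      resolution = resolution, n_iterations = 5))
  })
  memb <- as.integer(memb)

  # merge small communities into their most-connected neighbour
  min_size <- max(1L, ceiling(min_size_frac * n))
  repeat {
    sizes <- table(memb)
    small <- names(sizes)[sizes < min_size & sizes < max(sizes)]
    if (!length(small)) break
    el <- igraph::as_edgelist(graph, names = FALSE)
    ew <- igraph::E(graph)$weight
    moved <- FALSE
    for (cl in as.integer(small)) {
      inside <- memb[el[, 1]] == cl | memb[el[, 2]] == cl
      other <- ifelse(memb[el[inside, 1]] == cl, memb[el[inside, 2]],
                      memb[el[inside, 1]])
      valid <- other != cl
      if (!any(valid)) next
      target <- as.integer(names(which.max(
        tapply(ew[inside][valid], other[valid], sum))))
      memb[memb == cl] <- target
      moved <- TRUE
    }
    if (!moved) break
  }

  # relabel by decreasing size
  sizes <- sort(table(memb), decreasing = TRUE)
  new <- setNames(sprintf("C%02d", seq_along(sizes)), names(sizes))
  label <- factor(new[as.character(memb)], levels = unname(new))
  medians <- NULL
  if (!is.null(x)) {
    x <- as.matrix(x)
    medians <- t(vapply(levels(label), function(l)
      apply(x[label == l, , drop = FALSE], 2, median),
      numeric(ncol(x))))
  }
  structure(list(label = label,
                 sizes = as.integer(table(label)[levels(label)]),
                 medians = medians),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment>", length(levels(x$label)), "clusters over",
      length(x$label), "events\n")
  invisible(x)
}

#' Cluster pooled events from several samples
#'
#' Pools the arcsinh-scale marker matrices of all samples (mirroring
#' pooled clustering with per-sample assignment recovered by
#' membership), clusters them, and returns per-sample label vectors.
#'
#' @param events_list list of transformed [cell_events()].
#' @param k,resolution,seed,min_size_frac see [build_knn_graph()] and
#'   [community_cluster()].
#' @return list: `assignment` (the pooled `cluster_assignment`),
#'   `sample_id` (per pooled event), `per_sample` (list of label
#'   factors).
#' @export
cluster_samples <- function(events_list, k = 30L, resolution = 0.3,
                            seed = 1L, min_size_frac = 0.001) {
  mats <- lapply(events_list, function(e) {
    if (!e$transformed) stop("cluster on arcsinh-transformed events")
    e$exprs[, .marker_chan(e), drop = FALSE]
  })
  pooled <- do.call(rbind, mats)
  sample_id <- rep(vapply(events_list, `[[`, "", "sample_id"),
                   vapply(mats, nrow, 1L))
  g <- build_knn_graph(pooled, k = k)
  assignment <- community_cluster(g, resolution = resolution,
                                  seed = seed,
                                  min_size_frac = min_size_frac,
                                  x = pooled)
  per_sample <- split(assignment$label, sample_id)
  list(assignment = assignment, sample_id = sample_id,
       per_sample = per_sample)
}

#' Per-marker positivity thresholds
#'
#' Data-driven threshold per marker on the arcsinh scale: a
#' two-component 1-D split (2-means) when the marker is bimodal
#' (component centres at least `min_separation` apart), otherwise the
#' fixed `default` threshold. Mirrors automated placement of manual
#' positivity gates; any threshold can be overridden.
#'
#' @param profiles clusters x markers matrix (e.g. median profiles) or
#'   events x markers matrix.
#' @param default fallback threshold (default 1, i.e. raw ~5.9 at
#'   cofactor 5).
#' @param min_separation minimum centre separation to accept the
#'   bimodal split (default 1).
#' @param overrides named numeric of manual thresholds.
#' @return named numeric vector of thresholds.
#' @export
positivity_thresholds <- function(profiles, default = 1,
                                  min_separation = 1,
                                  overrides = NULL) {
  profiles <- as.matrix(profiles)
  thr <- vapply(seq_len(ncol(profiles)), function(j) {
    v <- profiles[, j]
    if (length(unique(v)) < 2L) return(default)
    km <- kmeans(v, centers = range(v))
    ctr <- sort(km$centers[, 1])
    if (diff(ctr) >= min_separation) mean(ctr) else default
  }, numeric(1))
  names(thr) <- colnames(profiles)
  if (!is.null(overrides)) thr[names(overrides)] <- overrides
  thr
}

#' Ordered lineage annotation rules
#'
#' First matching rule wins. Each rule is a `label` plus a predicate
#' over the per-marker positivity of a cluster's median profile. The
#' default order: granulocytes (CD66b+), T cells (CD3+), B cells
#' (CD19+), NK cells (CD56+), myeloid cells (CD14+/CD33+/CD11c+/CD16+),
#' otherwise unassigned.
#'
#' @return ordered list of `list(label, markers, predicate)`.
#' @export
annotation_rules <- function() {
  list(
    list(label = "granulocyte", markers = "CD66b",
         predicate = function(pos) isTRUE(pos["CD66b"])),
    list(label = "T", markers = "CD3",
         predicate = function(pos) isTRUE(pos["CD3"])),
    list(label = "B", markers = "CD19",
         predicate = function(pos) isTRUE(pos["CD19"])),
    list(label = "NK", markers = "CD56",
         predicate = function(pos) isTRUE(pos["CD56"])),
    list(label = "myeloid", markers = c("CD14", "CD33", "CD11c", "CD16"),
         predicate = function(pos)
           isTRUE(pos["CD14"]) || isTRUE(pos["CD33"]) ||
           isTRUE(pos["CD11c"]) || isTRUE(pos["CD16"])))
}

# subset refinement within a major type
.refine_subset <- function(major, pos) {
  p <- function(m) isTRUE(pos[m])
  if (major == "T") {
    if (p("TCRgd")) return("gdT")
    if (p("CD4") && !p("CD8a")) {
      if (p("CD25") && !p("CD127")) return("CD4 Treg")
      if (p("CCR7") && p("CD45RA")) return("CD4 Tn")
      if (p("CCR7")) return("CD4 Tcm")
      if (p("CD45RA")) return("CD4 Teff")
      return("CD4 Tem")
    }
    if (p("CD8a") && !p("CD4")) {
      if (p("CCR7") && p("CD45RA")) return("CD8 Tn")
      if (p("CCR7")) return("CD8 Tcm")
      if (p("CD45RA")) return("CD8 Teff")
      return("CD8 Tem")
    }
    if (p("CD4") && p("CD8a")) return("DPT")
    return("DNT")
  }
  if (major == "myeloid") {
    if (p("CD14") && !p("HLA-DR") && p("CD33")) return("M-MDSC")
    if (p("CD14") && p("CD16")) return("iMon")
    if (p("CD14")) return("cMon")
    if (p("CD16")) return("ncMon")
    if (p("CD11c") && p("HLA-DR")) return("mDC")
    return("myeloid other")
  }
  major
}

#' Annotate clusters with lineages and subsets
#'
#' Applies the ordered [annotation_rules()] to each cluster's median
#' marker profile (positivity from [positivity_thresholds()]), then
#' refines T clusters into CD4/CD8 functional subsets (Tn, Tcm, Tem,
#' Teff, Treg), gamma-delta and double-negative T, and myeloid clusters
#' into cMon/iMon/ncMon (by CD14/CD16), mDC and M-MDSC. Every cluster
#' receives exactly one major label (possibly `"unassigned"`).
#'
#' @param medians clusters x markers median profile matrix (arcsinh
#'   scale), e.g. `assignment$medians`.
#' @param thresholds named positivity thresholds; default derived from
#'   `medians`.
#' @param rules ordered rule list (default [annotation_rules()]).
#' @return data frame: `cluster`, `major`, `subset`.
#' @export
annotate_clusters <- function(medians,
                              thresholds = positivity_thresholds(medians),
                              rules = annotation_rules()) {
  medians <- as.matrix(medians)
  needed <- unique(unlist(lapply(rules, `[[`, "markers")))
  missing <- setdiff(needed, colnames(medians))
  if (length(missing))
    stop("annotation rules need missing marker(s): ",
         paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(medians)), function(i) {
    pos <- medians[i, ] > thresholds[colnames(medians)]
    major <- "unassigned"
    for (r in rules) if (r$predicate(pos)) { major <- r$label; break }
    subset <- if (major == "unassigned") "unassigned"
              else .refine_subset(major, pos)
    data.frame(cluster = rownames(medians)[i] %||% as.character(i),
               major = major, subset = subset, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' t-SNE embedding for visualisation
#'
#' @param x events x markers matrix (arcsinh scale).
#' @param seed integer seed (embedding is stochastic).
#' @param perplexity t-SNE perplexity; requires `nrow(x) >=
#'   4 * perplexity`.
#' @return n x 2 coordinate matrix.
#' @export
embed_tsne <- function(x, seed = 1L, perplexity = 30) {
  x <- as.matrix(x)
  if (nrow(x) < 4 * perplexity)
    stop("need at least 4 * perplexity events")
  withr_seed(seed, {
    Rtsne::Rtsne(x, perplexity = perplexity, check_duplicates = FALSE,
                 pca = FALSE, verbose = FALSE)$Y
  })
}

#' Per-sample relative frequency table
#'
#' Relative frequencies of labels per sample over a shared label space;
#' labels absent from a sample get frequency 0, so every row sums to 1
#' over the partition. Samples with zero cells in the denominator get
#' `NA` with a warning.
#'
#' @param sample_id character/factor per event.
#' @param label character/factor per event (cluster or subset label).
#' @param all_labels label space (default: observed labels).
#' @return samples x labels matrix of frequencies in `[0, 1]`.
#' @export
frequency_table <- function(sample_id, label, all_labels = NULL) {
  sample_id <- as.character(sample_id)
  label <- as.character(label)
  if (length(sample_id) != length(label))
    stop("sample_id and label must be parallel vectors")
  if (is.null(all_labels)) all_labels <- sort(unique(label))
  samples <- unique(sample_id)
  counts <- table(factor(sample_id, levels = samples),
                  factor(label, levels = all_labels))
  tot <- rowSums(counts)
  if (any(tot == 0))
    warning("sample(s) with zero cells in denominator: ",
            paste(samples[tot == 0], collapse = ", "), call. = FALSE)
  freq <- counts / ifelse(tot > 0, tot, NA)
  mat <- matrix(as.numeric(freq), nrow(counts), ncol(counts),
                dimnames = list(samples, all_labels))
  mat
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions up to relabelling.
#'
#' @param a,b parallel label vectors.
#' @return numeric scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
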