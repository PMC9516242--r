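# shared fixtures, all generated in code

# tiny single-cluster design with explicit profile
tiny_design <- function(n = c(NC = 1L, CAS = 1L, ASCVD = 1L),
                        cells = 100L, dispersion = 0.35, seed = 1L) {
  pan <- marker_panel("myeloid")
  loc <- setNames(rep(1.5, nrow(pan)), pan$marker)
  prof <- list(X1 = list(cluster_id = "X1", lineage = "cMon",
                         location = loc,
                         scale = setNames(rep(dispersion, nrow(pan)),
                                          pan$marker)))
  cohort_design(n_per_group = n, cells_per_sample = cells,
                panel = "myeloid", cluster_profiles = prof,
                base_weights = c(X1 = 1), seed = seed)
}

# one raw-scale sample from the default myeloid world
one_sample <- function(cells = 500L, seed = 1L) {
  d <- cohort_design(n_per_group = c(NC = 1L, CAS = 1L, ASCVD = 1L),
                     cells_per_sample = cells, seed = seed)
  generate_cohort(d)$events[[1]]
}

# explicit, widely separating gate thresholds for the synthetic world:
# clean events have DNA ~ N(600, 60), length ~ N(25, 3), viability < ~10
fixture_gate <- function() {
  gate_config(event_length_max = 40, dna_min = 300, dna_max = 1000,
              viability_max = 20)
}

# brute-force pairwise-concordance AUC (independent oracle)
pairwise_auc <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (max(y) > 1L) stop("binary only")
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# brute-force BH step-up (independent oracle)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) adj[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  adj
}
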