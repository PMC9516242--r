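#' Antibody panels and cluster phenotype profiles
#'
#' Two ~30-channel staining panels in the style of peripheral-blood
#' CyTOF immunophenotyping: a myeloid panel and a T-cell panel. Each
#' panel carries the conventional lineage markers used by the
#' annotation rules (CD45, CD66b, CD3, CD4, CD8, CD19, CD56, CD14,
#' CD16, CD33, ...) plus functional markers. Structural channels (DNA
#' iridium intercalators, cisplatin viability, event length, beads) are
#' appended by the generator and never treated as markers.
#'
#' @name panels
NULL

.lineage_markers <- c("CD45", "CD66b", "CD3", "CD4", "CD8a", "TCRgd",
                      "CD19", "CD56", "CD14", "CD16", "CD33", "CD11c",
                      "HLA-DR", "CD123", "CCR7", "CD45RA", "CD25",
                      "CD127")

.structural_channels <- data.frame(
  name = c("DNA1_Ir191", "DNA2_Ir193", "cisplatin_Pt194",
           "event_length", "bead_Ce140"),
  role = c("DNA", "DNA", "viability", "event_length", "bead"),
  stringsAsFactors = FALSE)

#' Marker panel definition
#'
#' @param panel `"myeloid"` or `"tcell"`.
#' @return data frame with columns `marker` and `role`
#'   (`"lineage"`/`"functional"`).
#' @export
marker_panel <- function(panel = c("myeloid", "tcell")) {
  panel <- match.arg(panel)
  markers <- switch(panel,
    myeloid = c("CD45", "CD66b", "CD3", "CD19", "CD56", "CD14", "CD16",
                "CD33", "CD11b", "CD11c", "HLA-DR", "CD64", "CD86",
                "CCR2", "CX3CR1", "CD38", "CD169", "CD123", "CD15",
                "CD163", "CD36", "PD-L1", "CD62L", "CD115", "S100A9"),
    tcell = c("CD45", "CD3", "CD4", "CD8a", "TCRgd", "CD19", "CD56",
              "CD14", "CD16", "CD33", "CD11c", "CD66b", "CD45RA",
              "CCR7", "CD27", "CD28", "CD25", "CD127", "FoxP3",
              "CD161", "CXCR3", "T-bet", "GranzymeB", "PD-1", "HLA-DR",
              "CD38", "CD11b", "CD57", "Fas"))
  data.frame(marker = markers,
             role = ifelse(markers %in% .lineage_markers, "lineage",
                           "functional"),
             stringsAsFactors = FALSE)
}

# positive/negative anchor levels on the arcsinh (cofactor 5) scale
.POS <- 4; .MID <- 2; .NEG <- 0.25

#' Default cluster phenotype profiles for a panel
#'
#' Builds a set of cluster profiles (per-marker location on the arcsinh
#' scale plus a common dispersion) whose lineage-marker patterns follow
#' the standard immunophenotyping rules, so that the annotation layer
#' can recover each cluster's lineage. The myeloid panel yields
#' monocyte subsets (cMon/iMon/ncMon by CD14/CD16), dendritic cells and
#' M-MDSC; the T panel yields CD4/CD8 functional subsets, gamma-delta T,
#' B, NK, monocyte and granulocyte clusters. Functional-marker levels
#' are drawn reproducibly from the anchor levels so clusters are
#' mutually distinguishable.
#'
#' @param panel `"myeloid"` or `"tcell"`.
#' @param n_clusters number of clusters; defaults to 15 (myeloid) /
#'   23 (tcell). Larger values recycle subset archetypes with fresh
#'   functional-marker patterns.
#' @param dispersion common per-marker SD on arcsinh scale
#'   (default 0.35).
#' @param seed integer seed for the reproducible functional patterns.
#' @return list of profiles; each has `cluster_id`, `lineage`,
#'   `location` (named numeric) and `scale` (named numeric).
#' @export
default_cluster_profiles <- function(panel = c("myeloid", "tcell"),
                                     n_clusters = NULL,
                                     dispersion = 0.35, seed = 2024L) {
  panel <- match.arg(panel)
  pan <- marker_panel(panel)
  if (is.null(n_clusters))
    n_clusters <- if (panel == "myeloid") 15L else 23L

  # archetypes: named lineage-marker settings; all other markers free
  archetypes <- if (panel == "myeloid") list(
    cMon   = c(CD45 = .POS, CD14 = .POS, CD16 = .NEG, CD33 = .POS,
               `HLA-DR` = .POS, CD11c = .MID),
    iMon   = c(CD45 = .POS, CD14 = .POS, CD16 = .POS, CD33 = .POS,
               `HLA-DR` = .POS, CD11c = .MID),
    ncMon  = c(CD45 = .POS, CD14 = .NEG, CD16 = .POS, CD33 = .POS,
               `HLA-DR` = .POS, CD11c = .MID),
    mDC    = c(CD45 = .POS, CD14 = .NEG, CD16 = .NEG, CD33 = .MID,
               CD11c = .POS, `HLA-DR` = .POS),
    MMDSC  = c(CD45 = .POS, CD14 = .POS, CD16 = .NEG, CD33 = .POS,
               `HLA-DR` = .NEG, CD11c = .NEG)
  ) else list(
    CD4T   = c(CD45 = .POS, CD3 = .POS, CD4 = .POS, CD8a = .NEG,
               TCRgd = .NEG),
    CD8T   = c(CD45 = .POS, CD3 = .POS, CD4 = .NEG, CD8a = .POS,
               TCRgd = .NEG),
    gdT    = c(CD45 = .POS, CD3 = .POS, CD4 = .NEG, CD8a = .NEG,
               TCRgd = .POS),
    DNT    = c(CD45 = .POS, CD3 = .POS, CD4 = .NEG, CD8a = .NEG,
               TCRgd = .NEG),
    B      = c(CD45 = .POS, CD3 = .NEG, CD19 = .POS, CD56 = .NEG),
    NK     = c(CD45 = .POS, CD3 = .NEG, CD19 = .NEG, CD56 = .POS,
               CD16 = .MID),
    Mono   = c(CD45 = .POS, CD3 = .NEG, CD19 = .NEG, CD56 = .NEG,
               CD14 = .POS, CD33 = .POS),
    Gran   = c(CD45 = .MID, CD66b = .POS, CD3 = .NEG, CD19 = .NEG,
               CD56 = .NEG)
  )
  lineages <- if (panel == "myeloid")
    c("cMon", "iMon", "ncMon", "mDC", "MMDSC")
  else c("CD4T", "CD8T", "gdT", "DNT", "B", "NK", "Mono", "Gran")
  prefix <- if (panel == "myeloid") "M" else "T"

  # lineage markers stay at their archetype (or negative) level; only
  # functional markers get free per-cluster patterns
  free <- setdiff(pan$marker[pan$role == "functional"],
                  unique(unlist(lapply(archetypes, names))))
  # memory phenotypes cycled over T clusters: (CCR7, CD45RA, CD25, CD127)
  mem <- list(Tn   = c(CCR7 = .POS, CD45RA = .POS, CD25 = .NEG, CD127 = .POS),
              Tcm  = c(CCR7 = .POS, CD45RA = .NEG, CD25 = .NEG, CD127 = .POS),
              Tem  = c(CCR7 = .NEG, CD45RA = .NEG, CD25 = .NEG, CD127 = .POS),
              Teff = c(CCR7 = .NEG, CD45RA = .POS, CD25 = .NEG, CD127 = .POS),
              Treg = c(CCR7 = .MID, CD45RA = .NEG, CD25 = .POS, CD127 = .NEG))
  profiles <- withr_seed(seed, {
    lapply(seq_len(n_clusters), function(i) {
      arch <- lineages[(i - 1L) %% length(lineages) + 1L]
      loc <- setNames(rep(.NEG, nrow(pan)), pan$marker)
      loc[names(archetypes[[arch]])] <- archetypes[[arch]]
      if (arch %in% c("CD4T", "CD8T")) {
        pattern <- mem[[((i - 1L) %/% length(lineages)) %% length(mem) + 1L]]
        loc[names(pattern)] <- pattern
      }
      # functional pattern: anchor levels drawn per cluster
      loc[free] <- sample(c(.NEG, .MID, .POS), length(free),
                          replace = TRUE, prob = c(0.5, 0.25, 0.25))
      list(cluster_id = sprintf("%s%02d", prefix, i), lineage = arch,
           location = loc,
           scale = setNames(rep(dispersion, nrow(pan)), pan$marker))
    })
  })
  names(profiles) <- vapply(profiles, `[[`, "", "cluster_id")
  profiles
}

# evaluate expr with a local RNG seed, restoring the global RNG state
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}
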