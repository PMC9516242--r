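#' Single-sample CyTOF event container
#'
#' Lightweight container for one sample's events x channels intensity
#' matrix plus channel metadata. Channel roles are `lineage`,
#' `functional`, `DNA`, `viability`, `event_length`, `bead`, or
#' `unassigned`.
#'
#' @param sample_id sample identifier.
#' @param exprs numeric events x channels matrix, nonnegative, with
#'   channel names as column names.
#' @param channels data frame with columns `name`, `role` matching the
#'   columns of `exprs`.
#' @param transformed logical: are marker channels on the arcsinh scale?
#' @return object of class `"cell_events"`.
#' @export
cell_events <- function(sample_id, exprs, channels,
                        transformed = FALSE) {
  exprs <- as.matrix(exprs)
  if (!identical(colnames(exprs), channels$name))
    stop("channel metadata must match exprs columns")
  if (any(exprs < 0, na.rm = TRUE) && !transformed)
    stop("raw intensities must be nonnegative")
  structure(list(sample_id = sample_id, exprs = exprs,
                 channels = channels, transformed = transformed),
            class = "cell_events")
}

#' @export
print.cell_events <- function(x, ...) {
  cat("<cell_events> sample", x$sample_id, ":", nrow(x$exprs), "events x",
      ncol(x$exprs), "channels",
      if (x$transformed) "(arcsinh)" else "(raw)", "\n")
  invisible(x)
}

#' @export
dim.cell_events <- function(x) dim(x$exprs)

# channel indices by role
.chan <- function(events, role) {
  which(events$channels$role %in% role)
}

# marker (= lineage + functional) channel indices
.marker_chan <- function(events) .chan(events, c("lineage", "functional"))

#' Cohort design for the synthetic generator
#'
#' Describes a three-group (NC / CAS / ASCVD) peripheral-blood cohort:
#' group sizes, cells per sample, the marker panel and cluster
#' phenotypes, group-dependent effects on cluster abundance (log-fold
#' shifts of mixture weights) and marker expression (additive shifts on
#' the arcsinh scale), the clinical covariate model and the per-segment
#' stenosis model. Defaults emulate the published cohort: group sizes
#' 13/38/32, clinical covariate means and SDs from the printed cohort
#' table, CAS stenosis below 50%, ASCVD stenosis 50-99%.
#'
#' Between-sample abundance variation is Dirichlet with concentration
#' `concentration` (default 200) around the group-level weights; event
#' intensities are Gaussian on the arcsinh scale (cofactor 5), mapped
#' back through the inverse transform and truncated at zero on the raw
#' scale.
#'
#' @param n_per_group named integer vector `c(NC=, CAS=, ASCVD=)`.
#' @param cells_per_sample events per sample (default 2000; desk scale).
#' @param panel `"myeloid"` or `"tcell"`.
#' @param cluster_profiles list of cluster profiles; default
#'   [default_cluster_profiles()] for the panel.
#' @param base_weights named cluster mixture weights (summing to 1);
#'   default: geometric decay over clusters, normalised.
#' @param frequency_effects clusters x groups matrix of log-fold shifts
#'   applied to `base_weights` (default all zero).
#' @param marker_effects optional list `cluster -> group -> named
#'   numeric` additive arcsinh-scale shifts (default none).
#' @param clinical_model list `continuous` (variable x group means/sds)
#'   and `binary` (variable x group probabilities); default from
#'   [cohort_table()] for age, BMI, TC, TG, HDL, LDL and the printed
#'   comorbidity rates.
#' @param concentration Dirichlet concentration for between-sample
#'   abundance variation.
#' @param cofactor arcsinh cofactor used to map locations to raw scale.
#' @param seed integer seed.
#' @return object of class `"cohort_design"`.
#' @export
cohort_design <- function(n_per_group = c(NC = 13L, CAS = 38L, ASCVD = 32L),
                          cells_per_sample = 2000L,
                          panel = c("myeloid", "tcell"),
                          cluster_profiles = NULL,
                          base_weights = NULL,
                          frequency_effects = NULL,
                          marker_effects = NULL,
                          clinical_model = NULL,
                          concentration = 200,
                          cofactor = 5,
                          seed = 1L) {
  panel <- match.arg(panel)
  if (any(n_per_group <= 0)) stop("group counts must be positive")
  if (is.null(names(n_per_group)) && length(n_per_group) == 3L)
    names(n_per_group) <- c("NC", "CAS", "ASCVD")
  if (is.null(cluster_profiles))
    cluster_profiles <- default_cluster_profiles(panel)
  ids <- names(cluster_profiles)
  k <- length(ids)
  pan <- marker_panel(panel)
  for (pr in cluster_profiles)
    if (!all(pan$marker %in% names(pr$location)) ||
        any(pr$scale < 0))
      stop("every cluster profile needs a location for every panel ",
           "marker and nonnegative dispersions")
  if (is.null(base_weights)) {
    base_weights <- setNames(0.85^seq_len(k), ids)
    base_weights <- base_weights / sum(base_weights)
  }
  if (abs(sum(base_weights) - 1) > 1e-8)
    stop("base_weights must sum to 1")
  if (is.null(frequency_effects))
    frequency_effects <- matrix(0, k, length(n_per_group),
                                dimnames = list(ids, names(n_per_group)))
  if (is.null(clinical_model))
    clinical_model <- default_clinical_model()
  structure(list(n_per_group = n_per_group,
                 cells_per_sample = as.integer(cells_per_sample),
                 panel = panel, cluster_profiles = cluster_profiles,
                 base_weights = base_weights,
                 frequency_effects = frequency_effects,
                 marker_effects = marker_effects,
                 clinical_model = clinical_model,
                 concentration = concentration, cofactor = cofactor,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Default clinical covariate model (printed cohort summaries)
#'
#' Continuous covariates (age, BMI, TC, TG, HDL, LDL) use the printed
#' per-group means and SDs; binary comorbidities use the printed
#' per-group rates.
#'
#' @return list with `continuous` and `binary` model tables.
#' @export
default_clinical_model <- function() {
  tab <- cohort_table()
  keep <- c("age", "BMI", "TC", "TG", "HDL", "LDL")
  cont <- tab$continuous[match(keep, tab$continuous$variable), ]
  rownames(cont) <- NULL
  bin <- tab$categorical
  bin$p_NC <- bin$yes_NC / tab$n[["NC"]]
  bin$p_CAS <- bin$yes_CAS / tab$n[["CAS"]]
  bin$p_ASCVD <- bin$yes_ASCVD / tab$n[["ASCVD"]]
  list(continuous = cont,
       binary = bin[, c("variable", "p_NC", "p_CAS", "p_ASCVD")])
}

# Dirichlet draw centred on w with concentration c
.rdirichlet <- function(w, conc) {
  g <- rgamma(length(w), shape = conc * w)
  if (sum(g) == 0) return(w) # degenerate guard
  g / sum(g)
}

# structural-channel simulators (raw scale)
.sim_structural <- function(n) {
  cbind(DNA1_Ir191 = pmax(0, rnorm(n, 600, 60)),
        DNA2_Ir193 = pmax(0, rnorm(n, 550, 55)),
        cisplatin_Pt194 = abs(rnorm(n, 0, 2)),
        event_length = pmax(1, rnorm(n, 25, 3)),
        bead_Ce140 = abs(rnorm(n, 0, 1)))
}

#' Generate a synthetic cohort
#'
#' Draws, for each sample: its true cluster mixture weights (Dirichlet
#' around the group-level weights, which are the base weights shifted
#' by the design's per-group log-fold effects), per-cell cluster
#' labels, and marker intensities (Gaussian on the arcsinh scale at the
#' cluster's location, then mapped through `cofactor * sinh(z)` to the
#' raw scale and truncated at zero). Structural channels (DNA,
#' viability, event length, bead) are appended on the raw scale.
#' Clinical covariates are drawn per group from the design's clinical
#' model. Deterministic given the design seed.
#'
#' @param design a [cohort_design()].
#' @return list with `events` (list of [cell_events()]), `clinical`
#'   (data frame: sample_id, group, covariates), and `truth` (list:
#'   `labels` per sample, `weights` samples x clusters matrix of true
#'   mixture weights, `group` per sample).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  pan <- marker_panel(design$panel)
  ids <- names(design$cluster_profiles)
  groups <- rep(names(design$n_per_group), design$n_per_group)
  sample_ids <- sprintf("S%03d", seq_along(groups))
  chan_meta <- rbind(
    data.frame(name = pan$marker, role = pan$role,
               stringsAsFactors = FALSE),
    .structural_channels)

  events <- vector("list", length(groups))
  labels <- vector("list", length(groups))
  weights <- matrix(NA_real_, length(groups), length(ids),
                    dimnames = list(sample_ids, ids))

  for (s in seq_along(groups)) {
    g <- groups[s]
    w_g <- design$base_weights * exp(design$frequency_effects[, g])
    w_g <- w_g / sum(w_g)
    w_s <- .rdirichlet(w_g, design$concentration)
    weights[s, ] <- w_s
    n <- design$cells_per_sample
    lab <- sample(ids, n, replace = TRUE, prob = w_s)
    z <- matrix(NA_real_, n, nrow(pan),
                dimnames = list(NULL, pan$marker))
    for (cl in unique(lab)) {
      rows <- which(lab == cl)
      pr <- design$cluster_profiles[[cl]]
      loc <- pr$location[pan$marker]
      eff <- design$marker_effects[[cl]][[g]]
      if (!is.null(eff)) loc[names(eff)] <- loc[names(eff)] + eff
      z[rows, ] <- rep(loc, each = length(rows)) +
        matrix(rnorm(length(rows) * nrow(pan)), length(rows)) *
        rep(pr$scale[pan$marker], each = length(rows))
    }
    raw <- design$cofactor * sinh(z)
    raw[raw < 0] <- 0
    mat <- cbind(raw, .sim_structural(n))
    colnames(mat) <- chan_meta$name
    events[[s]] <- cell_events(sample_ids[s], mat, chan_meta)
    labels[[s]] <- lab
  }
  names(events) <- names(labels) <- sample_ids

  clinical <- .generate_clinical(design, sample_ids, groups)
  list(events = events, clinical = clinical,
       truth = list(labels = labels, weights = weights,
                    group = setNames(groups, sample_ids)))
}

.generate_clinical <- function(design, sample_ids, groups) {
  cm <- design$clinical_model
  out <- data.frame(sample_id = sample_ids, group = groups,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cm$continuous))) {
    row <- cm$continuous[i, ]
    mu <- c(NC = row$mean_NC, CAS = row$mean_CAS, ASCVD = row$mean_ASCVD)
    sd <- c(NC = row$sd_NC, CAS = row$sd_CAS, ASCVD = row$sd_ASCVD)
    out[[row$variable]] <- rnorm(length(groups), mu[groups], sd[groups])
  }
  for (i in seq_len(nrow(cm$binary))) {
    row <- cm$binary[i, ]
    p <- c(NC = row$p_NC, CAS = row$p_CAS, ASCVD = row$p_ASCVD)
    out[[row$variable]] <- rbinom(length(groups), 1L, p[groups])
  }
  out
}

#' Inject doublet and dead-cell artifacts
#'
#' Flags `round(rate * n)` events per artifact class. Doublets get
#' doubled DNA intensity and 1.8x event length; dead cells get a high
#' cisplatin (viability) intensity well above the live distribution.
#' Truth flags are recorded on the returned object.
#'
#' @param events a raw-scale [cell_events()].
#' @param doublet_rate,dead_rate fractions in `[0, 1]`.
#' @param seed integer seed.
#' @return `cell_events` with modified intensities and logical
#'   attribute vectors `doublet` and `dead` in `$truth`.
#' @export
inject_artifacts <- function(events, doublet_rate = 0, dead_rate = 0,
                             seed = 1L) {
  stopifnot(doublet_rate >= 0, doublet_rate <= 1,
            dead_rate >= 0, dead_rate <= 1)
  if (events$transformed) stop("inject artifacts on the raw scale")
  set.seed(seed)
  n <- nrow(events$exprs)
  doublet <- dead <- rep(FALSE, n)
  pool <- seq_len(n)
  n_dbl <- round(doublet_rate * n)
  if (n_dbl > 0) {
    idx <- sample(pool, n_dbl)
    doublet[idx] <- TRUE
    pool <- setdiff(pool, idx)
    dna <- .chan(events, "DNA")
    len <- .chan(events, "event_length")
    events$exprs[idx, dna] <- events$exprs[idx, dna] * 2
    events$exprs[idx, len] <- events$exprs[idx, len] * 1.8
  }
  n_dead <- round(dead_rate * n)
  if (n_dead > 0) {
    idx <- sample(pool, n_dead)
    dead[idx] <- TRUE
    viab <- .chan(events, "viability")
    events$exprs[idx, viab] <- pmax(0, rnorm(n_dead, 80, 10))
  }
  events$truth <- list(doublet = doublet, dead = dead)
  events
}

#' Generate per-segment coronary stenosis profiles
#'
#' NC samples are lesion-free (all segments 0, hence Gensini 0). CAS
#' samples get 1-2 lesions with stenosis uniform on (5, 50) (below the
#' 50% inclusion threshold); ASCVD samples get 2-4 lesions uniform on
#' [50, 99]. Lesioned segments are drawn uniformly from the segment
#' vocabulary.
#'
#' @param groups character vector of group labels (`NC`/`CAS`/`ASCVD`)
#'   per patient, e.g. `truth$group` from [generate_cohort()].
#' @param patient_ids optional identifiers (default `names(groups)` or
#'   P001...).
#' @param seed integer seed.
#' @return long data frame: `patient_id`, `group`, `segment`,
#'   `stenosis_pct` (one row per segment, lesion-free segments 0).
#' @export
generate_stenosis_profiles <- function(groups, patient_ids = NULL,
                                       seed = 1L) {
  groups <- as.character(unname(groups))
  if (!all(groups %in% c("NC", "CAS", "ASCVD")))
    stop("groups must be NC, CAS or ASCVD")
  if (is.null(patient_ids))
    patient_ids <- sprintf("P%03d", seq_along(groups))
  set.seed(seed)
  segs <- gensini_segments()
  rows <- lapply(seq_along(groups), function(i) {
    pct <- setNames(rep(0, length(segs)), segs)
    g <- groups[i]
    if (g == "CAS") {
      lesions <- sample(segs, sample(1:2, 1))
      pct[lesions] <- runif(length(lesions), 5, 49.99)
    } else if (g == "ASCVD") {
      lesions <- sample(segs, sample(2:4, 1))
      pct[lesions] <- runif(length(lesions), 50, 99)
    }
    data.frame(patient_id = patient_ids[i], group = g, segment = segs,
               stenosis_pct = unname(pct), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
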