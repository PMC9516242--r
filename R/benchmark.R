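#' Benchmark world for the model pipeline
#'
#' The published headline model accuracies are not reproducible without
#' the (undeposited) patient cohort, so the model layer is validated on
#' a fixed synthetic world: 45 samples (15 per group), 30 immune
#' features (cluster frequencies), 4 of them planted as discriminative
#' between controls and patients, and 6 clinical features (age, BMI,
#' TC, TG, HDL, LDL) of which 2 (TC, HDL) carry group signal. Base
#' mixture weights are uniform and the planted log-fold shifts come in
#' weight-balanced pairs (the weight gained by an up-shifted cluster
#' equals the weight lost by its partner), so compositional closure
#' does not leak abundance signal into non-planted clusters: they are
#' exact nulls at the group level. Effect sizes (0.5-1.7 log-fold) are
#' comparable to the strongest reported subset shifts. Clinical
#' effects are the printed group means for TC and HDL with the
#' remaining covariates held at the control-group distribution.
#'
#' @param seed integer seed for the design.
#' @param cells_per_sample events per sample (default 2000).
#' @return a [cohort_design()] with attributes `planted_immune`
#'   (cluster ids) and `planted_clinical` (variable names).
#' @export
model_benchmark_design <- function(seed = 1L, cells_per_sample = 2000L) {
  profiles <- default_cluster_profiles("myeloid", n_clusters = 30L)
  ids <- names(profiles)
  planted <- c("M02", "M06", "M11", "M13")
  fx <- matrix(0, length(ids), 3,
               dimnames = list(ids, c("NC", "CAS", "ASCVD")))
  # weight-balanced pairs: (e^a - 1) = (1 - e^-b) within each pair
  fx["M02", c("CAS", "ASCVD")] <- 0.6
  fx["M06", c("CAS", "ASCVD")] <- log(2 - exp(0.6))   # -1.7346
  fx["M11", c("CAS", "ASCVD")] <- 0.5
  fx["M13", c("CAS", "ASCVD")] <- log(2 - exp(0.5))   # -1.0461

  cm <- default_clinical_model()
  flat <- !(cm$continuous$variable %in% c("TC", "HDL"))
  cm$continuous$mean_CAS[flat] <- cm$continuous$mean_NC[flat]
  cm$continuous$mean_ASCVD[flat] <- cm$continuous$mean_NC[flat]
  cm$continuous$sd_CAS[flat] <- cm$continuous$sd_NC[flat]
  cm$continuous$sd_ASCVD[flat] <- cm$continuous$sd_NC[flat]

  design <- cohort_design(
    n_per_group = c(NC = 15L, CAS = 15L, ASCVD = 15L),
    cells_per_sample = cells_per_sample, panel = "myeloid",
    cluster_profiles = profiles,
    base_weights = setNames(rep(1 / 30, 30), ids),
    frequency_effects = fx, clinical_model = cm, seed = seed)
  attr(design, "planted_immune") <- planted
  attr(design, "planted_clinical") <- c("TC", "HDL")
  design
}

#' Materialise model-ready features from a generated cohort
#'
#' Computes the immune feature table (per-sample cluster frequencies
#' from the generator's true labels), the clinical feature matrix
#' (age, BMI, TC, TG, HDL, LDL), and the binary task labels.
#'
#' @param cohort output of [generate_cohort()].
#' @param task `"dp"` (NC vs pooled CAS+ASCVD) or `"dpp"` (CAS vs
#'   ASCVD; NC samples dropped).
#' @return list: `immune` (samples x clusters frequency matrix),
#'   `clinical` (samples x 6 matrix), `labels` (2-level factor,
#'   positive class second), `group`.
#' @export
cohort_model_features <- function(cohort, task = c("dp", "dpp")) {
  task <- match.arg(task)
  truth <- cohort$truth
  sample_ids <- names(truth$labels)
  n_cells <- vapply(truth$labels, length, 1L)
  immune <- frequency_table(rep(sample_ids, n_cells),
                            unlist(truth$labels),
                            all_labels = colnames(truth$weights))
  clin_vars <- c("age", "BMI", "TC", "TG", "HDL", "LDL")
  clinical <- as.matrix(cohort$clinical[, clin_vars])
  rownames(clinical) <- cohort$clinical$sample_id
  group <- truth$group[sample_ids]
  if (task == "dp") {
    labels <- factor(ifelse(group == "NC", "NC", "AS"),
                     levels = c("NC", "AS"))
    keep <- rep(TRUE, length(group))
  } else {
    keep <- group != "NC"
    labels <- factor(group[keep], levels = c("CAS", "ASCVD"))
  }
  list(immune = immune[keep, , drop = FALSE],
       clinical = clinical[keep, , drop = FALSE],
       labels = labels, group = group[keep])
}

#' Read a cohort design from a YAML configuration
#'
#' Recognised fields: `n_per_group` (named list), `cells_per_sample`,
#' `panel`, `concentration`, `cofactor`, `seed`, `n_clusters`,
#' `dispersion`. Cluster profiles and effects beyond these knobs are
#' constructed with package defaults.
#'
#' @param path YAML file path.
#' @return a [cohort_design()].
#' @export
cohort_design_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  profiles <- NULL
  if (!is.null(cfg$n_clusters) || !is.null(cfg$dispersion))
    profiles <- default_cluster_profiles(
      cfg$panel %||% "myeloid",
      n_clusters = cfg$n_clusters,
      dispersion = cfg$dispersion %||% 0.35)
  cohort_design(
    n_per_group = unlist(cfg$n_per_group %||%
                           c(NC = 13L, CAS = 38L, ASCVD = 32L)),
    cells_per_sample = cfg$cells_per_sample %||% 2000L,
    panel = cfg$panel %||% "myeloid",
    cluster_profiles = profiles,
    concentration = cfg$concentration %||% 200,
    cofactor = cfg$cofactor %||% 5,
    seed = cfg$seed %||% 1L)
}

#' Write a generated cohort to disk
#'
#' Events as per-sample CSV (with channel sidecars), the clinical
#' table and stenosis profiles as CSV, truth as JSON.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param stenosis optional long stenosis table from
#'   [generate_stenosis_profiles()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, stenosis = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ev in cohort$events)
    write_events(ev, file.path(dir, paste0(ev$sample_id, ".csv")))
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  if (!is.null(stenosis))
    write.csv(stenosis, file.path(dir, "stenosis.csv"),
              row.names = FALSE)
  jsonlite::write_json(
    list(weights = as.data.frame(cohort$truth$weights),
         group = as.list(cohort$truth$group)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
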