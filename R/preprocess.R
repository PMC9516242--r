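#' CyTOF event preprocessing
#'
#' The preprocessing chain applied to each sample before clustering:
#' bead-based sensitivity normalization, debris/dead-cell/doublet
#' gating on event length, DNA content and cisplatin viability, then
#' arcsinh transformation (cofactor 5) of the marker channels. Gates
#' operate on raw intensities; the fixed order is
#' normalize -> gate -> transform.
#'
#' @name cytof_preprocess
NULL

#' Write / read events as CSV
#'
#' CSV with one header row of channel names; channel roles travel in a
#' JSON sidecar (`<path>.channels.json`) and are re-derived from the
#' panel when the sidecar is missing. Unknown channels get role
#' `"unassigned"` with a warning.
#'
#' @param events a [cell_events()].
#' @param path output CSV path.
#' @return `write_events` returns `path` invisibly; `read_events`
#'   returns a `cell_events`.
#' @export
write_events <- function(events, path) {
  write.csv(as.data.frame(events$exprs), path, row.names = FALSE)
  jsonlite::write_json(
    list(sample_id = events$sample_id, channels = events$channels,
         transformed = events$transformed),
    paste0(path, ".channels.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_events
#' @param sample_id sample identifier to use when no sidecar exists.
#' @param panel optional panel name used to assign roles when no
#'   sidecar exists.
#' @export
read_events <- function(path, sample_id = NULL, panel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  mat <- as.matrix(read.csv(path, check.names = FALSE))
  sidecar <- paste0(path, ".channels.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    channels <- as.data.frame(meta$channels)
    return(cell_events(sample_id %||% meta$sample_id, mat, channels,
                       transformed = isTRUE(meta$transformed)))
  }
  channels <- data.frame(name = colnames(mat),
                         role = channel_roles(colnames(mat), panel),
                         stringsAsFactors = FALSE)
  cell_events(sample_id %||% basename(path), mat, channels)
}

#' Assign channel roles from channel names
#'
#' @param names character vector of channel names.
#' @param panel optional panel name for marker role lookup.
#' @return character vector of roles.
#' @export
channel_roles <- function(names, panel = NULL) {
  roles <- rep(NA_character_, length(names))
  roles[grepl("Ir19[13]|DNA", names, ignore.case = TRUE)] <- "DNA"
  roles[grepl("Pt194|cisplatin|viab", names, ignore.case = TRUE)] <- "viability"
  roles[grepl("length", names, ignore.case = TRUE)] <- "event_length"
  roles[grepl("bead|Ce140", names, ignore.case = TRUE)] <- "bead"
  if (!is.null(panel)) {
    pan <- marker_panel(panel)
    hit <- match(names, pan$marker)
    roles[is.na(roles) & !is.na(hit)] <- pan$role[hit[is.na(roles) &
                                                        !is.na(hit)]]
  } else {
    roles[is.na(roles) & names %in% .lineage_markers] <- "lineage"
    roles[is.na(roles)] <- ifelse(
      grepl("^(CD|CCR|CXCR|HLA|TCR|PD|Fox|T-bet|Granzyme|Fas|S100)",
            names[is.na(roles)]), "functional", NA)
  }
  if (anyNA(roles)) {
    warning("unknown channel(s): ",
            paste(names[is.na(roles)], collapse = ", "),
            "; role set to 'unassigned'", call. = FALSE)
    roles[is.na(roles)] <- "unassigned"
  }
  roles
}

#' Append calibration bead events and simulate sensitivity drift
#'
#' `add_bead_events` interleaves `n_beads` bead events (high bead
#' channel, low marker/DNA signal) at random acquisition positions.
#' `apply_sensitivity_drift` multiplies mass channels (markers + bead)
#' by a linearly decaying sensitivity over acquisition order, emulating
#' instrument drift; `total_decay = 0.2` means the last event is
#' acquired at 80% sensitivity.
#'
#' @param events a raw-scale [cell_events()].
#' @param n_beads number of bead events to add.
#' @param seed integer seed.
#' @return modified `cell_events`.
#' @export
add_bead_events <- function(events, n_beads, seed = 1L) {
  set.seed(seed)
  n <- nrow(events$exprs)
  bead <- matrix(abs(rnorm(n_beads * ncol(events$exprs), 0, 0.5)),
                 n_beads, dimnames = list(NULL, colnames(events$exprs)))
  bead[, .chan(events, "bead")] <- pmax(0, rnorm(n_beads, 500, 25))
  bead[, .chan(events, "event_length")] <- pmax(1, rnorm(n_beads, 15, 2))
  pos <- sort(sample(n + n_beads, n_beads))
  out <- matrix(NA_real_, n + n_beads, ncol(events$exprs),
                dimnames = list(NULL, colnames(events$exprs)))
  out[pos, ] <- bead
  out[-pos, ] <- events$exprs
  events$exprs <- out
  events
}

#' @rdname add_bead_events
#' @param total_decay fractional sensitivity loss at the end of the
#'   acquisition.
#' @export
apply_sensitivity_drift <- function(events, total_decay = 0.2) {
  n <- nrow(events$exprs)
  gain <- 1 - total_decay * (seq_len(n) - 1) / max(1, n - 1)
  mass <- c(.marker_chan(events), .chan(events, "bead"))
  events$exprs[, mass] <- events$exprs[, mass] * gain
  events
}

#' Bead-based sensitivity normalization (simplified)
#'
#' Identifies bead events on the bead channel (midpoint between the
#' bead-positive and bead-negative modes), splits the acquisition into
#' time windows (row order = acquisition order), and rescales every
#' mass channel in each window so the window's bead medians match the
#' reference medians. Bead events are removed from the output.
#'
#' @param events raw-scale [cell_events()] containing bead events.
#' @param bead_reference optional named per-channel reference medians;
#'   default: bead medians of the first window.
#' @param n_windows number of time windows (default 10).
#' @return `cell_events` with beads removed and mass channels rescaled.
#'   Passes through with a warning when no bead events are found.
#' @export
bead_normalize <- function(events, bead_reference = NULL,
                           n_windows = 10L) {
  bead_ch <- .chan(events, "bead")
  if (length(bead_ch) != 1L) stop("need exactly one bead channel")
  b <- events$exprs[, bead_ch]
  # beads sit far above the cell background on the bead channel
  if (length(b) == 0L || max(b) < 100) {
    warning("no bead events found; returning input unchanged",
            call. = FALSE)
    return(events)
  }
  is_bead <- b > max(b) / 2
  mass <- c(.marker_chan(events), bead_ch)
  n <- nrow(events$exprs)
  window <- ceiling(seq_len(n) / (n / n_windows))
  window <- pmin(window, n_windows)
  ref <- bead_reference
  if (is.null(ref)) {
    first <- is_bead & window == 1L
    ref <- apply(events$exprs[first, mass, drop = FALSE], 2, median)
  }
  bead_medians <- matrix(NA_real_, n_windows, length(mass),
                         dimnames = list(NULL, colnames(events$exprs)[mass]))
  for (w in seq_len(n_windows)) {
    wb <- is_bead & window == w
    if (!any(wb)) next
    med <- apply(events$exprs[wb, mass, drop = FALSE], 2, median)
    fac <- ifelse(med > 0, ref / med, 1)
    rows <- window == w
    events$exprs[rows, mass] <-
      sweep(events$exprs[rows, mass, drop = FALSE], 2, fac, `*`)
    bead_medians[w, ] <- apply(
      events$exprs[wb, mass, drop = FALSE], 2, median)
  }
  report <- list(n_beads = sum(is_bead), reference = ref,
                 bead_medians = bead_medians)
  events$exprs <- events$exprs[!is_bead, , drop = FALSE]
  attr(events, "bead_report") <- report
  events
}

#' Gating configuration
#'
#' Thresholds for the debris/doublet/dead-cell gates, all on the raw
#' intensity scale. The published procedure is manual; the automated
#' default derives robust thresholds (median +/- `k` MAD) from the data
#' itself, overridable field by field.
#'
#' @param event_length_max maximum event length.
#' @param dna_min,dna_max DNA intercalator window.
#' @param viability_max maximum cisplatin intensity (live cells low).
#' @return object of class `"gate_config"`.
#' @export
gate_config <- function(event_length_max = Inf, dna_min = -Inf,
                        dna_max = Inf, viability_max = Inf) {
  if (dna_min >= dna_max) stop("dna_min must be below dna_max")
  structure(list(event_length_max = event_length_max, dna_min = dna_min,
                 dna_max = dna_max, viability_max = viability_max),
            class = "gate_config")
}

#' @rdname gate_config
#' @param events a raw-scale [cell_events()] used to derive thresholds.
#' @param k robustness multiplier on the MAD (default 4).
#' @export
default_gate_config <- function(events, k = 4) {
  len <- events$exprs[, .chan(events, "event_length")[1]]
  dna <- events$exprs[, .chan(events, "DNA")[1]]
  viab <- events$exprs[, .chan(events, "viability")[1]]
  gate_config(
    event_length_max = median(len) + k * stats::mad(len),
    dna_min = max(0, median(dna) - k * stats::mad(dna)),
    dna_max = median(dna) + k * stats::mad(dna),
    viability_max = median(viab) + k * stats::mad(viab))
}

#' Gate out debris, doublets and dead cells
#'
#' Retains events passing all thresholds (conjunctive rules): event
#' length below `event_length_max`, every DNA channel within
#' `[dna_min, dna_max]`, viability below `viability_max`. The report
#' attributes removals per rule; because the rules are conjunctive the
#' outcome is order-independent.
#'
#' @param events raw-scale [cell_events()] with DNA, viability and
#'   event-length channels.
#' @param cfg a [gate_config()]; default [default_gate_config()].
#' @return list with `events` (gated `cell_events`) and `report` (per
#'   rule: flagged counts; `exclusive` counts flagged by that rule
#'   only; `multi` flagged by >1 rule; `removed`, `retained`).
#' @export
gate_events <- function(events, cfg = default_gate_config(events)) {
  if (events$transformed) stop("gates operate on raw intensities")
  dna_ch <- .chan(events, "DNA")
  viab_ch <- .chan(events, "viability")
  len_ch <- .chan(events, "event_length")
  if (!length(dna_ch) || length(viab_ch) != 1L || length(len_ch) != 1L)
    stop("gating needs DNA, viability and event_length channels")

  fail_len <- events$exprs[, len_ch] > cfg$event_length_max
  dna <- events$exprs[, dna_ch, drop = FALSE]
  fail_dna <- apply(dna < cfg$dna_min | dna > cfg$dna_max, 1, any)
  fail_viab <- events$exprs[, viab_ch] > cfg$viability_max
  fails <- cbind(event_length = fail_len, dna = fail_dna,
                 viability = fail_viab)
  n_rules <- rowSums(fails)
  keep <- n_rules == 0L

  report <- list(
    flagged = colSums(fails),
    exclusive = colSums(fails & n_rules == 1L),
    multi = sum(n_rules > 1L),
    removed = sum(!keep),
    retained = sum(keep))

  events$exprs <- events$exprs[keep, , drop = FALSE]
  if (!is.null(events$truth))
    events$truth <- lapply(events$truth, `[`, keep)
  list(events = events, report = report)
}

#' Arcsinh transformation of marker channels
#'
#' Applies `x -> asinh(x / cofactor)` to lineage and functional
#' channels; DNA, viability, event-length and bead channels are left on
#' the raw scale.
#'
#' @param events a [cell_events()].
#' @param cofactor positive cofactor (default 5).
#' @return transformed `cell_events` (`transformed = TRUE`).
#' @export
arcsinh_transform <- function(events, cofactor = 5) {
  if (cofactor <= 0) stop("cofactor must be positive")
  if (events$transformed) stop("events already transformed")
  mk <- .marker_chan(events)
  events$exprs[, mk] <- asinh(events$exprs[, mk] / cofactor)
  events$transformed <- TRUE
  events
}

#' Run the full preprocessing chain on one sample
#'
#' normalize (when beads present) -> gate -> arcsinh.
#'
#' @inheritParams gate_events
#' @inheritParams arcsinh_transform
#' @param normalize attempt bead normalization first (default FALSE).
#' @return list with `events` (clean, transformed) and `report`.
#' @export
preprocess_events <- function(events, cfg = NULL, cofactor = 5,
                              normalize = FALSE) {
  if (normalize) events <- bead_normalize(events)
  if (is.null(cfg)) cfg <- default_gate_config(events)
  gated <- gate_events(events, cfg)
  list(events = arcsinh_transform(gated$events, cofactor),
       report = gated$report)
}
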