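#' Gensini coronary plaque-burden scoring
#'
#' The Gensini system quantifies angiographic plaque burden as a weighted
#' sum over coronary segments: each segment's percent reduction in lumen
#' diameter is mapped to a geometric severity score (1, 2, 4, 8, 16, 32
#' for reductions of up to 25, 50, 75, 90, 99 and 100 percent) and
#' multiplied by a fixed segment-importance weight (e.g. x5 for the left
#' main). A vessel with no stenosis contributes 0.
#'
#' @name gensini
NULL

# segment vocabulary and printed weighting factors
.gensini_weights <- c(
  LM = 5, LAD_prox = 2.5, LAD_mid = 1.5, LAD_dist = 1,
  D1 = 1, D2 = 0.5, LCX_prox = 2.5, LCX_dist = 1,
  RCA_prox = 1, RCA_mid = 1, RCA_dist = 1)

# right-closed severity breakpoints of the canonical system
.gensini_breaks <- c(0, 25, 50, 75, 90, 99, 100)
.gensini_scores <- c(1L, 2L, 4L, 8L, 16L, 32L)

#' Gensini severity score for a stenosis percentage
#'
#' Step function on the canonical breakpoints, right-closed: 0 scores 0,
#' (0, 25] scores 1, (25, 50] scores 2, (50, 75] scores 4, (75, 90]
#' scores 8, (90, 99] scores 16 and (99, 100] scores 32.
#'
#' @param stenosis_pct numeric vector of lumen-diameter reductions in
#'   `[0, 100]`.
#' @return integer vector of severity scores.
#' @examples
#' severity_score(c(0, 25, 50, 75, 90, 99, 100))
#' @export
severity_score <- function(stenosis_pct) {
  stenosis_pct <- as.numeric(stenosis_pct)
  if (anyNA(stenosis_pct) || any(stenosis_pct < 0 | stenosis_pct > 100))
    stop("stenosis_pct must be in [0, 100]")
  out <- integer(length(stenosis_pct))
  nz <- stenosis_pct > 0
  idx <- findInterval(stenosis_pct[nz], .gensini_breaks,
                      left.open = TRUE, rightmost.closed = TRUE)
  out[nz] <- .gensini_scores[idx]
  out
}

#' Segment weighting factor
#'
#' @param segment character vector of segment labels; the vocabulary is
#'   `LM`, `LAD_prox`, `LAD_mid`, `LAD_dist`, `D1`, `D2`, `LCX_prox`,
#'   `LCX_dist`, `RCA_prox`, `RCA_mid`, `RCA_dist`.
#' @return numeric vector of weights.
#' @examples
#' segment_weight(c("LM", "D2", "RCA_mid"))
#' @export
segment_weight <- function(segment) {
  segment <- as.character(segment)
  unknown <- setdiff(segment, names(.gensini_weights))
  if (length(unknown))
    stop("unknown coronary segment(s): ", paste(unknown, collapse = ", "))
  unname(.gensini_weights[segment])
}

#' @describeIn gensini Coronary segment vocabulary, in anatomical order.
#' @export
gensini_segments <- function() names(.gensini_weights)

#' Compute a Gensini score from a per-segment stenosis profile
#'
#' @param profile named numeric vector or data frame with columns
#'   `segment` and `stenosis_pct`; names/segments must come from
#'   [gensini_segments()]. Segments absent from the profile are treated
#'   as lesion-free.
#' @param patient_id optional identifier carried into the result.
#' @return A list of class `"gensini_score"` with `patient_id`, `total`,
#'   and a `contributions` data frame (segment, stenosis_pct, severity,
#'   weight, contribution).
#' @examples
#' gensini_score(c(LAD_prox = 75))           # 4 x 2.5 = 10
#' gensini_score(c(LM = 50, RCA_dist = 100)) # 2x5 + 32x1 = 42
#' @export
gensini_score <- function(profile, patient_id = NA_character_) {
  if (is.data.frame(profile)) {
    seg <- as.character(profile$segment)
    pct <- as.numeric(profile$stenosis_pct)
  } else {
    seg <- names(profile)
    pct <- as.numeric(profile)
  }
  if (is.null(seg) || anyDuplicated(seg))
    stop("profile must map distinct segments to stenosis percentages")
  w <- segment_weight(seg) # validates vocabulary
  sev <- severity_score(pct)
  contrib <- data.frame(
    segment = seg, stenosis_pct = pct, severity = sev, weight = w,
    contribution = sev * w, stringsAsFactors = FALSE)
  structure(
    list(patient_id = patient_id, total = sum(contrib$contribution),
         contributions = contrib),
    class = "gensini_score")
}

#' @export
print.gensini_score <- function(x, ...) {
  cat("Gensini score", if (!is.na(x$patient_id)) paste0("[", x$patient_id, "]"),
      "=", x$total, "\n")
  invisible(x)
}

#' Score a long-format stenosis table
#'
#' @param stenosis data frame with columns `patient_id`, `segment`,
#'   `stenosis_pct` (one row per lesion), e.g. as read from CSV.
#' @return data frame with one row per patient: `patient_id`,
#'   `gensini_total`.
#' @export
gensini_score_table <- function(stenosis) {
  stopifnot(all(c("patient_id", "segment", "stenosis_pct") %in%
                  names(stenosis)))
  ids <- unique(as.character(stenosis$patient_id))
  totals <- vapply(ids, function(id) {
    rows <- stenosis[stenosis$patient_id == id, , drop = FALSE]
    gensini_score(rows, patient_id = id)$total
  }, numeric(1))
  data.frame(patient_id = ids, gensini_total = unname(totals),
             stringsAsFactors = FALSE)
}
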