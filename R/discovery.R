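#' Find diametric within-subject visit pairs
#'
#' A diametric pair is two consecutive visits of one subject whose anxiety
#' state flips between the LOW pole (SAS-4 <= 40) and the HIGH pole
#' (SAS-4 >= 60; SEVERE visits sit on the HIGH pole since severity is a
#' refinement of the high-anxiety state). Visits separated by an
#' INTERMEDIATE visit do not pair.
#'
#' @param visits data.frame with subject_id, visit_index, sample_id and a
#'   `state` column of [labelState] labels (or an [AnxietyCohort-class],
#'   from which visits and labels are derived).
#' @return data.frame with one row per pair: subject_id, sample_low,
#'   sample_high, order ("low_to_high" or "high_to_low").
#' @export
findDiametricPairs <- function(visits) {
  if (is(visits, "AnxietyCohort")) {
    v <- visitData(visits)
    v$state <- stateLabels(visits)
    visits <- v
  }
  pole <- ifelse(visits$state == "LOW", "L",
          ifelse(visits$state %in% c("HIGH", "SEVERE"), "H", NA))
  out <- list()
  for (s in unique(visits$subject_id)) {
    idx <- which(visits$subject_id == s)
    idx <- idx[order(visits$visit_index[idx])]
    for (k in seq_len(length(idx) - 1)) {
      a <- idx[k]; b <- idx[k + 1]
      if (is.na(pole[a]) || is.na(pole[b]) || pole[a] == pole[b]) next
      if (pole[a] == "L") {
        out[[length(out) + 1]] <- data.frame(
          subject_id = s, sample_low = visits$sample_id[a],
          sample_high = visits$sample_id[b], order = "low_to_high",
          stringsAsFactors = FALSE)
      } else {
        out[[length(out) + 1]] <- data.frame(
          subject_id = s, sample_low = visits$sample_id[b],
          sample_high = visits$sample_id[a], order = "high_to_low",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(subject_id = character(), sample_low = character(),
                      sample_high = character(), order = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Concordance of one probeset with anxiety state across one diametric pair
#'
#' DE (differential expression): +1 if expression rises from the LOW to the
#' HIGH visit by at least the log fold-change threshold, -1 if it falls by
#' at least that much, 0 otherwise. AP (Absent/Present): +1 for an
#' Absent-to-Present call flip from LOW to HIGH, -1 for Present-to-Absent,
#' 0 otherwise.
#'
#' @param low_value,high_value expression at the LOW and HIGH visit (DE), or
#'   logical Present calls (AP).
#' @param method "DE" or "AP".
#' @param de_fold_threshold log2 fold-change threshold for DE (default
#'   0.263, a 1.2-fold change).
#' @return integer in {-1, 0, +1}.
#' @export
pairConcordance <- function(low_value, high_value, method = c("DE", "AP"),
                            de_fold_threshold = 0.263) {
  method <- match.arg(method)
  if (method == "DE") {
    d <- high_value - low_value
    ifelse(d >= de_fold_threshold, 1L, ifelse(d <= -de_fold_threshold, -1L, 0L))
  } else {
    if (is.null(low_value) || is.null(high_value) ||
        anyNA(low_value) || anyNA(high_value))
      stop("AP concordance requires detection calls for both visits")
    ifelse(!low_value & high_value, 1L, ifelse(low_value & !high_value, -1L, 0L))
  }
}

#' Map a percent-of-maximum tracking score to internal discovery points
#'
#' Probesets scoring at least 33% of the maximum raw score get 2 points,
#' at least 50% get 4, and at least 80% get 6 (all cuts inclusive).
#'
#' @param percent percent of maximum raw score, 0-100.
#' @return integer points in {0, 2, 4, 6}.
#' @export
discoveryPoints <- function(percent) {
  ifelse(percent >= 80, 6L, ifelse(percent >= 50, 4L,
    ifelse(percent >= 33, 2L, 0L)))
}

#' Score one probeset's anxiety-state tracking over all diametric pairs
#'
#' The direction of change in high anxiety is the sign of the summed pair
#' concordances (ties resolve to "increased"); the raw score counts the
#' pairs concordant with that direction; percent-of-maximum divides by the
#' total number of diametric pairs in the cohort, and maps to internal
#' points via [discoveryPoints].
#'
#' @param concordances integer vector in {-1, 0, 1}, one per pair.
#' @param n_pairs total diametric pairs in the cohort (>= 1).
#' @return list with direction, raw_score, percent_of_max, internal_points.
#' @export
discoveryScore <- function(concordances, n_pairs = length(concordances)) {
  if (n_pairs < 1) stop("n_pairs must be at least 1")
  s <- sum(concordances)
  direction <- if (s >= 0) "increased" else "decreased"
  raw <- sum(concordances == (if (direction == "increased") 1L else -1L))
  pct <- 100 * raw / n_pairs
  list(direction = direction, raw_score = raw, percent_of_max = pct,
       internal_points = discoveryPoints(pct))
}

#' Step 1: score every probeset for tracking anxiety state
#'
#' Runs the DE analysis (and, when detection calls are available, the AP
#' analysis) over all diametric pairs of the discovery arm and returns one
#' row per probeset and method. A probeset may earn both a DE and an AP
#' score; downstream scoring keeps the maximum.
#'
#' @param cohort the discovery [AnxietyCohort-class] (expression on the
#'   scale the DE threshold refers to, typically z-scored log2 values).
#' @param pairs diametric pairs from [findDiametricPairs]; computed from
#'   `cohort` when NULL.
#' @param methods subset of c("DE", "AP").
#' @param de_fold_threshold log fold-change threshold for DE calls.
#' @return data.frame: probeset, method, direction, raw_score,
#'   percent_of_max, internal_points.
#' @export
scoreDiscovery <- function(cohort, pairs = NULL, methods = c("DE", "AP"),
                           de_fold_threshold = 0.263) {
  if (is.null(pairs)) pairs <- findDiametricPairs(cohort)
  if (nrow(pairs) == 0) stop("no diametric pairs in the discovery cohort")
  x <- exprsMatrix(cohort)
  n_pairs <- nrow(pairs)
  res <- list()
  if ("DE" %in% methods) {
    d <- x[, pairs$sample_high, drop = FALSE] - x[, pairs$sample_low, drop = FALSE]
    conc <- matrix(0L, nrow(d), ncol(d))
    conc[d >= de_fold_threshold] <- 1L
    conc[d <= -de_fold_threshold] <- -1L
    res$DE <- .summariseConcordance(conc, rownames(x), "DE", n_pairs)
  }
  if ("AP" %in% methods) {
    calls <- detectionCalls(cohort)
    if (!is.null(calls)) {
      lo <- calls[, pairs$sample_low, drop = FALSE]
      hi <- calls[, pairs$sample_high, drop = FALSE]
      conc <- matrix(0L, nrow(calls), ncol(lo))
      conc[!lo & hi] <- 1L
      conc[lo & !hi] <- -1L
      res$AP <- .summariseConcordance(conc, rownames(x), "AP", n_pairs)
    }
  }
  if (!length(res)) stop("no scoring method could be applied")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.summariseConcordance <- function(conc, probesets, method, n_pairs) {
  s <- rowSums(conc)
  direction <- ifelse(s >= 0, "increased", "decreased")
  raw <- ifelse(direction == "increased", rowSums(conc == 1L),
                rowSums(conc == -1L))
  pct <- 100 * raw / n_pairs
  data.frame(probeset = probesets, method = method, direction = direction,
             raw_score = as.integer(raw), percent_of_max = pct,
             internal_points = discoveryPoints(pct),
             stringsAsFactors = FALSE)
}
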