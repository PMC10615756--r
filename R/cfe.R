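.STEP4_TARGETS <- c("state_sas4", "state_stai", "hosp_first_year",
                    "hosp_all_future")

#' Final Convergent Functional Evidence score (CFE4)
#'
#' Composes all four steps: discovery (up to 6), CFG prioritization
#' (up to 12), validation (up to 6), and the four Step-4 prediction
#' categories (up to 3 points each under the maximum rule), for a total of
#' up to 36 points -- 24 from the study's own cohorts and 12 from
#' literature evidence.
#'
#' @param discovery_points,cfg_points,validation_points first-three-step
#'   components.
#' @param step4_points numeric vector of per-category points (each in
#'   0..3; up to four categories, missing categories counted 0).
#' @return CFE4 score.
#' @export
cfe4Score <- function(discovery_points, cfg_points, validation_points,
                      step4_points) {
  cfe3 <- cfe3Score(discovery_points, cfg_points, validation_points)
  if (length(step4_points) > 4)
    stop("at most four Step-4 prediction categories")
  .checkRange(step4_points, 0, 3, "step4_points")
  cfe3 + sum(step4_points)
}

#' Assemble the per-biomarker scorecard after all four steps
#'
#' @param validated output of [scoreValidation] (carries discovery, CFG and
#'   validation points plus cfe3).
#' @param predictions output of [testPrediction].
#' @param alpha significance level for Step-4 point scoring.
#' @return scorecard data.frame with per-target Step-4 points, cfe3 and
#'   cfe4, sorted by cfe4 descending.
#' @export
buildScorecard <- function(validated, predictions, alpha = 0.05) {
  card <- validated
  for (tg in .STEP4_TARGETS) {
    col <- paste0("pts_", tg)
    card[[col]] <- vapply(card$probeset, function(ps) {
      step4Points(predictions[predictions$probeset == ps &
                                predictions$target == tg, , drop = FALSE],
                  alpha = alpha)
    }, integer(1))
  }
  pts_cols <- paste0("pts_", .STEP4_TARGETS)
  card$cfe4 <- card$cfe3 + rowSums(card[, pts_cols, drop = FALSE])
  card <- card[order(-card$cfe4, -card$cfe3, card$probeset), , drop = FALSE]
  rownames(card) <- NULL
  card
}

#' Select the top biomarker panel from a scorecard
#'
#' Filters on CFE3 >= `gate_cfe3` (default 8, one third of the 24-point
#' post-validation maximum), then optionally keeps the `panel_size` best
#' by CFE4 (ties broken by CFE3, then probeset id).
#'
#' @param cards scorecard from [buildScorecard] (needs cfe3, cfe4,
#'   probeset; direction and gene_symbol are carried through).
#' @param gate_cfe3 inclusive CFE3 cutoff.
#' @param panel_size optional panel size.
#' @return the ordered panel subset.
#' @export
selectTopPanel <- function(cards, gate_cfe3 = 8, panel_size = NULL) {
  stopifnot(gate_cfe3 >= 0)
  keep <- cards[cards$cfe3 >= gate_cfe3, , drop = FALSE]
  if ("cfe4" %in% colnames(keep)) {
    keep <- keep[order(-keep$cfe4, -keep$cfe3, keep$probeset), , drop = FALSE]
  } else {
    keep <- keep[order(-keep$cfe3, keep$probeset), , drop = FALSE]
  }
  if (!is.null(panel_size)) keep <- utils::head(keep, panel_size)
  rownames(keep) <- NULL
  keep
}

#' Direction-aligned panel aggregate (BioM-N score)
#'
#' The polygenic panel predictor for a visit: the mean of the panel
#' members' z-scored expression after aligning directions (markers
#' decreased in high anxiety are negated), so higher aggregates mean more
#' anxiety-like expression. Missing members are dropped.
#'
#' @param panel data.frame with probeset and direction columns.
#' @param z_values named numeric vector (or single-column matrix) of
#'   z-scored expression for one visit, names are probesets.
#' @return list(score, n_used, n_missing).
#' @export
panelAggregate <- function(panel, z_values) {
  z <- z_values[panel$probeset]
  sgn <- ifelse(panel$direction == "increased", 1, -1)
  ok <- !is.na(z)
  if (!any(ok)) stop("no panel member measured for this visit")
  list(score = mean(z[ok] * sgn[ok]), n_used = sum(ok), n_missing = sum(!ok))
}
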