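#' Longitudinal biomarker features for one subject
#'
#' From a visit series of (time, level): the level at the most recent
#' visit, the maximum level, the slope into the most recent visit, and the
#' maximum between-visit slope (levels per year). The combined predictor
#' used in longitudinal testing is formed downstream by z-scoring each
#' feature across the subjects of an evaluation stratum and averaging.
#'
#' @param times visit times in decimal years, strictly increasing.
#' @param levels expression levels at those visits.
#' @return list(last_level, max_level, last_slope, max_slope), or NULL for
#'   series with fewer than two visits (signalled via attribute).
#' @export
longitudinalFeatures <- function(times, levels) {
  if (length(times) < 2) return(NULL)
  if (any(duplicated(times)) || is.unsorted(times, strictly = TRUE))
    stop("visit times must be strictly increasing")
  slopes <- diff(levels) / diff(times)
  list(last_level = levels[length(levels)],
       max_level = max(levels),
       last_slope = slopes[length(slopes)],
       max_slope = max(slopes))
}

#' ROC AUC and one-sided significance for a single biomarker
#'
#' AUC is the Mann-Whitney U statistic scaled by the number of
#' positive-negative pairs, ties counted one half, computed after
#' orienting values so the discovery direction predicts the positive class
#' (values of decreased markers are negated). The p-value is the one-sided
#' Mann-Whitney test (normal approximation with tie correction).
#'
#' @param values biomarker levels.
#' @param labels logical positive-class labels.
#' @param direction "increased" or "decreased" in high anxiety.
#' @return list(auc, p, n_pos, n_total).
#' @export
aucPredict <- function(values, labels, direction = "increased") {
  labels <- as.logical(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be non-empty (", n_pos, " positives, ",
         n_neg, " negatives)")
  v <- if (direction == "decreased") -values else values
  r <- rank(v)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  p <- suppressWarnings(stats::wilcox.test(v[labels], v[!labels],
                                           alternative = "greater",
                                           exact = FALSE)$p.value)
  list(auc = auc, p = p, n_pos = n_pos, n_total = n_pos + n_neg)
}

#' Proportional-hazards prediction of future hospitalizations
#'
#' Univariate Cox regression of time to first future hospitalization on a
#' biomarker, standardized to unit SD so the reported ratio (labelled
#' "Cox regression Odds Ratio" in the source literature; a hazard ratio)
#' is per 1-SD increase. Values of decreased markers are negated before
#' standardization, so ratios above 1 mean prediction in the discovery
#' direction.
#'
#' @param values biomarker levels, one per observation.
#' @param time follow-up time (years) to event or censoring.
#' @param event logical event indicator.
#' @param direction "increased" or "decreased".
#' @return list(ratio, p, n_events, n_total, converged).
#' @export
hazardPredict <- function(values, time, event, direction = "increased") {
  keep <- !is.na(values) & !is.na(time) & !is.na(event) & time > 0
  values <- values[keep]; time <- time[keep]; event <- as.logical(event[keep])
  if (sum(event) < 1) stop("no events in the stratum")
  v <- if (direction == "decreased") -values else values
  s <- stats::sd(v)
  if (is.na(s) || s == 0)
    return(list(ratio = NA_real_, p = NA_real_, n_events = sum(event),
                n_total = length(v), converged = FALSE))
  z <- (v - mean(v)) / s
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ z),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit) || !is.finite(stats::coef(fit)[1]))
    return(list(ratio = NA_real_, p = NA_real_, n_events = sum(event),
                n_total = length(v), converged = FALSE))
  sm <- summary(fit)
  list(ratio = unname(exp(stats::coef(fit)[1])),
       p = unname(sm$coefficients[1, "Pr(>|z|)"]),
       n_events = sum(event), n_total = length(v), converged = TRUE)
}

#' Step-4 points for one prediction category from stratified results
#'
#' A biomarker earns 3 points for a category if it significantly predicts
#' in all subjects, 2 points if in a gender stratum, and 1 point if in a
#' gender-by-diagnosis stratum -- the maximum applicable, not a sum.
#'
#' @param results data.frame with columns `stratum_type` (one of "ALL",
#'   "gender", "gender_dx") and `p`.
#' @param alpha significance level (default 0.05).
#' @return integer points in {0, 1, 2, 3}.
#' @export
step4Points <- function(results, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(results) || nrow(results) == 0) return(0L)
  sig <- results[!is.na(results$p) & results$p < alpha, , drop = FALSE]
  if (any(sig$stratum_type == "ALL")) return(3L)
  if (any(sig$stratum_type == "gender")) return(2L)
  if (any(sig$stratum_type == "gender_dx")) return(1L)
  0L
}

#' Bonferroni survival flag for a tested biomarker p-value
#'
#' @param p p-value.
#' @param n_biomarkers number of candidate biomarkers tested (default 95).
#' @return TRUE iff p < 0.05 / n_biomarkers (strict).
#' @export
bonferroniFlag <- function(p, n_biomarkers = 95) {
  stopifnot(n_biomarkers >= 1)
  !is.na(p) & p < 0.05 / n_biomarkers
}

# evaluation strata of a test cohort: ALL; each gender; gender x diagnosis
# including the pooled PSYCHOSIS (SZ + SZA) stratum
.buildStrata <- function(visits) {
  strata <- list(list(name = "ALL", type = "ALL",
                      idx = seq_len(nrow(visits))))
  for (g in intersect(.GENDERS, unique(visits$gender)))
    strata[[length(strata) + 1]] <-
      list(name = g, type = "gender", idx = which(visits$gender == g))
  dx_groups <- c(as.list(.DIAGNOSES), list(c("SZ", "SZA")))
  names(dx_groups) <- c(.DIAGNOSES, "PSYCHOSIS")
  for (g in .GENDERS) for (dxn in names(dx_groups)) {
    idx <- which(visits$gender == g & visits$diagnosis %in% dx_groups[[dxn]])
    if (length(idx))
      strata[[length(strata) + 1]] <-
        list(name = paste(g, dxn, sep = "-"), type = "gender_dx", idx = idx)
  }
  strata
}

# per-subject longitudinal combined score for one probeset within a stratum:
# z-score each of the four features across subjects, then average
.longitudinalCombined <- function(x_row, visits, idx) {
  sub <- split(idx, visits$subject_id[idx])
  sub <- sub[vapply(sub, length, integer(1)) >= 2]
  if (length(sub) == 0) return(NULL)
  feats <- lapply(sub, function(ii) {
    ii <- ii[order(visits$visit_time[ii])]
    longitudinalFeatures(visits$visit_time[ii], x_row[ii])
  })
  fm <- do.call(rbind, lapply(feats, function(f) unlist(f)))
  if (nrow(fm) < 2) return(NULL)
  fsd <- apply(fm, 2, stats::sd)
  fz <- scale(fm)
  fz[, is.na(fsd) | fsd == 0] <- 0  # constant feature adds nothing
  data.frame(subject_id = names(sub),
             combined = rowMeans(fz),
             last_idx = vapply(sub, function(ii)
               ii[which.max(visits$visit_time[ii])], integer(1)),
             stringsAsFactors = FALSE)
}

#' Step 4: stratified state and trait predictive testing
#'
#' Tests each candidate biomarker in the independent test cohort against
#' four targets: high anxiety state (SAS-4 >= 60 visits vs the rest),
#' clinically severe anxiety state (SEVERE visits vs the rest), first-year
#' hospitalization with anxiety after a visit (ROC AUC for all three), and
#' all future hospitalizations with anxiety (Cox proportional hazards).
#' Each target is evaluated in every stratum (ALL, by gender, by
#' gender-by-diagnosis including pooled PSYCHOSIS), cross-sectionally
#' (visit-level values) and longitudinally (per-subject combined score
#' over levels and slopes, labelled/timed at the most recent visit).
#' Strata with fewer than 2 positives or 2 negatives (AUC) or fewer than
#' 3 events (Cox) are skipped.
#'
#' @param test_cohort z-scored test [AnxietyCohort-class].
#' @param candidates data.frame with probeset and direction columns.
#' @param alpha significance level for downstream point scoring.
#' @param n_biomarkers Bonferroni denominator (defaults to the number of
#'   candidates).
#' @return tidy data.frame, one row per probeset x target x stratum x mode.
#' @export
testPrediction <- function(test_cohort, candidates, alpha = 0.05,
                           n_biomarkers = nrow(candidates)) {
  visits <- visitData(test_cohort)
  lab <- stateLabels(test_cohort)
  x <- exprsMatrix(test_cohort)
  strata <- .buildStrata(visits)
  targets <- list(
    state_sas4 = list(kind = "auc", pos = visits$sas4 >= 60),
    state_stai = list(kind = "auc", pos = lab == "SEVERE"),
    hosp_first_year = list(kind = "auc", pos = visits$followup_first_year_hosp),
    hosp_all_future = list(kind = "cox",
                           event = visits$followup_any_future_hosp,
                           time = ifelse(
                             !is.na(visits$followup_any_future_hosp) &
                               visits$followup_any_future_hosp,
                             visits$time_to_first_hosp, visits$censor_time))
  )
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    ps <- candidates$probeset[i]
    dirn <- candidates$direction[i]
    xr <- x[ps, ]
    for (tg in names(targets)) {
      t <- targets[[tg]]
      for (st in strata) {
        idx <- st$idx
        # cross-sectional: visits as observations
        row <- .evalTarget(t, xr, visits, idx, dirn)
        if (!is.null(row))
          out[[length(out) + 1]] <- cbind(
            data.frame(probeset = ps, target = tg, stratum = st$name,
                       stratum_type = st$type, mode = "cross_sectional",
                       stringsAsFactors = FALSE), row)
        # longitudinal: per-subject combined feature
        lf <- .longitudinalCombined(xr, visits, idx)
        if (!is.null(lf)) {
          row <- .evalTarget(t, stats::setNames(lf$combined, NULL),
                             visits, lf$last_idx, "increased",
                             values_are_scores = TRUE)
          if (!is.null(row))
            out[[length(out) + 1]] <- cbind(
              data.frame(probeset = ps, target = tg, stratum = st$name,
                         stratum_type = st$type, mode = "longitudinal",
                         stringsAsFactors = FALSE), row)
        }
      }
    }
  }
  if (!length(out)) stop("no stratum was large enough to test")
  res <- do.call(rbind, out)
  res$bonferroni_flag <- bonferroniFlag(res$p, n_biomarkers)
  rownames(res) <- NULL
  res
}

# evaluate one target in one stratum; returns NULL when too small.
# values_are_scores: values are subject-level combined scores already
# oriented in the discovery direction (direction handled upstream).
.evalTarget <- function(t, values, visits, idx, direction,
                        values_are_scores = FALSE) {
  v <- if (values_are_scores) values else values[idx]
  if (t$kind == "auc") {
    labs <- t$pos[idx]
    ok <- !is.na(labs) & !is.na(v)
    if (sum(labs[ok]) < 2 || sum(!labs[ok]) < 2) return(NULL)
    r <- aucPredict(v[ok], labs[ok], direction)
    data.frame(statistic = r$auc, p = r$p, n_pos = r$n_pos,
               n_total = r$n_total)
  } else {
    ev <- t$event[idx]; tm <- t$time[idx]
    ok <- !is.na(ev) & !is.na(tm) & !is.na(v) & tm > 0
    if (sum(ev[ok]) < 3) return(NULL)
    r <- hazardPredict(v[ok], tm[ok], ev[ok], direction)
    if (!r$converged) return(NULL)
    data.frame(statistic = r$ratio, p = r$p, n_pos = r$n_events,
               n_total = r$n_total)
  }
}
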