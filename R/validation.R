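#' Stepwise-change check across low, high, and severe anxiety groups
#'
#' A biomarker is stepwise changed when its group means order strictly in
#' the discovery direction: low < high < severe for markers increased in
#' high anxiety, low > high > severe for decreased markers. Ties fail.
#'
#' @param low_mean,high_mean,severe_mean group means of z-scored expression.
#' @param direction "increased" or "decreased".
#' @return logical.
#' @export
stepwiseChange <- function(low_mean, high_mean, severe_mean,
                           direction = c("increased", "decreased")) {
  direction <- match.arg(direction)
  if (anyNA(c(low_mean, high_mean, severe_mean)))
    stop("all three group means are required")
  if (direction == "increased")
    low_mean < high_mean & high_mean < severe_mean
  else
    low_mean > high_mean & high_mean > severe_mean
}

#' One-way fixed-effects ANOVA p-value across the three anxiety groups
#'
#' @param groups list of numeric vectors (each of length >= 2).
#' @return p-value in (0, 1]; a between-group F of 0 gives p = 1.
#' @export
anovaP <- function(groups) {
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 observations")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  stats::oneway.test(y ~ g, var.equal = TRUE)$p.value
}

#' Validation points from the stepwise check and ANOVA p-value
#'
#' Non-stepwise biomarkers score 0. Stepwise biomarkers score 2, rising to
#' 4 when nominally significant (p < 0.05) and to 6 when surviving
#' Bonferroni correction for the number of candidates tested
#' (p < 0.05 / n_candidates). The Bonferroni tier can be capped away with
#' `max_points = 4`.
#'
#' @param stepwise logical from [stepwiseChange].
#' @param p ANOVA p-value.
#' @param n_candidates candidates carried into validation (>= 1).
#' @param alpha nominal significance level.
#' @param max_points 6 (default) or 4.
#' @return integer points in {0, 2, 4, 6}.
#' @export
validationPoints <- function(stepwise, p, n_candidates, alpha = 0.05,
                             max_points = 6) {
  if (n_candidates < 1) stop("n_candidates must be at least 1")
  pts <- ifelse(!stepwise, 0L,
         ifelse(p >= alpha, 2L,
         ifelse(p >= alpha / n_candidates, 4L, 6L)))
  pmin(pts, as.integer(max_points))
}

#' Convergent Functional Evidence score after the first three steps (CFE3)
#'
#' @param discovery_points,cfg_points,validation_points component scores
#'   (discovery and validation in {0, 2, 4, 6}; CFG in `[0, 12]`).
#' @return CFE3 = sum of the three components (maximum 24).
#' @export
cfe3Score <- function(discovery_points, cfg_points, validation_points) {
  .checkRange(discovery_points, 0, 6, "discovery_points")
  .checkRange(cfg_points, 0, 12, "cfg_points")
  .checkRange(validation_points, 0, 6, "validation_points")
  discovery_points + cfg_points + validation_points
}

.checkRange <- function(x, lo, hi, what) {
  if (any(x < lo | x > hi))
    stop(what, " outside [", lo, ", ", hi, "]")
  invisible(TRUE)
}

#' Step 3: validate candidates in the clinically severe anxiety cohort
#'
#' For each candidate, compares z-scored expression means across three
#' groups of visits -- discovery LOW, discovery HIGH (including SEVERE
#' pole visits), and validation SEVERE -- testing for stepwise change in
#' the discovery direction and for group differences by one-way ANOVA.
#' The validation cohort is expected on the discovery cohort's
#' normalization scale (frozen z-scoring), keeping the step out-of-sample.
#'
#' @param discovery_cohort,validation_cohort z-scored
#'   [AnxietyCohort-class] objects.
#' @param candidates output of [selectCandidates].
#' @param alpha,max_points passed to [validationPoints].
#' @return `candidates` with anova_p, stepwise, validation_points, cfe3.
#' @export
scoreValidation <- function(discovery_cohort, validation_cohort, candidates,
                            alpha = 0.05, max_points = 6) {
  lab_d <- stateLabels(discovery_cohort)
  lab_v <- stateLabels(validation_cohort)
  low_ids <- colnames(discovery_cohort)[lab_d == "LOW"]
  high_ids <- colnames(discovery_cohort)[lab_d %in% c("HIGH", "SEVERE")]
  sev_ids <- colnames(validation_cohort)[lab_v == "SEVERE"]
  if (!length(low_ids) || !length(high_ids) || !length(sev_ids))
    stop("one of the low/high/severe groups is empty")
  xd <- exprsMatrix(discovery_cohort)
  xv <- exprsMatrix(validation_cohort)
  n_cand <- nrow(candidates)
  res <- candidates
  res$stepwise <- NA
  res$anova_p <- NA_real_
  for (i in seq_len(n_cand)) {
    ps <- candidates$probeset[i]
    g <- list(low = xd[ps, low_ids], high = xd[ps, high_ids],
              severe = xv[ps, sev_ids])
    res$stepwise[i] <- stepwiseChange(mean(g$low), mean(g$high),
                                      mean(g$severe),
                                      candidates$direction[i])
    res$anova_p[i] <- anovaP(g)
  }
  res$validation_points <- validationPoints(res$stepwise, res$anova_p,
                                            n_candidates = n_cand,
                                            alpha = alpha,
                                            max_points = max_points)
  res$cfe3 <- cfe3Score(res$discovery_points, res$cfg_points,
                        res$validation_points)
  res
}
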