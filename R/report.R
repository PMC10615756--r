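#' Reference digitization thresholds for a biomarker panel
#'
#' For every panel member, the average z-scored expression in a
#' high-reference group of visits and in a low-reference group (for the
#' anxiety-state report those are SAS-4 >= 60 and SAS-4 <= 40 visits; for
#' the hospitalization reports, visits followed vs not followed by
#' hospitalization). A marker is concordant when the high-group average
#' sits on the expected side of the low-group average given its discovery
#' direction; only concordant markers enter percentile denominators.
#'
#' @param cohort a z-scored reference [AnxietyCohort-class].
#' @param panel data.frame with probeset and direction columns.
#' @param high_idx,low_idx indices (or logical masks) of the reference
#'   visit groups.
#' @return data.frame: probeset, direction, high_group_mean,
#'   low_group_mean, concordant.
#' @export
referenceThresholds <- function(cohort, panel, high_idx, low_idx) {
  x <- exprsMatrix(cohort)
  hi <- rowMeans(x[panel$probeset, high_idx, drop = FALSE])
  lo <- rowMeans(x[panel$probeset, low_idx, drop = FALSE])
  conc <- ifelse(panel$direction == "increased", hi > lo, hi < lo)
  data.frame(probeset = panel$probeset, direction = panel$direction,
             high_group_mean = hi, low_group_mean = lo, concordant = conc,
             stringsAsFactors = FALSE)
}

#' Digitize a biomarker value against its reference thresholds
#'
#' For markers increased in high anxiety: 1 if the z-scored value is at or
#' above the high-group average, 0 if at or below the low-group average,
#' 0.5 in between. The rule is mirrored for decreased markers.
#'
#' @param z z-scored expression value(s).
#' @param high_group_mean,low_group_mean reference averages.
#' @param direction "increased" or "decreased".
#' @return value(s) in {0, 0.5, 1}.
#' @export
digitizeBiomarker <- function(z, high_group_mean, low_group_mean,
                              direction = "increased") {
  inc <- direction == "increased"
  hi_side <- ifelse(inc, z >= high_group_mean, z <= high_group_mean)
  lo_side <- ifelse(inc, z <= low_group_mean, z >= low_group_mean)
  ifelse(hi_side, 1, ifelse(lo_side, 0, 0.5))
}

#' Polygenic risk percentile from digitized biomarker scores
#'
#' @param scores digitized scores in {0, 0.5, 1} of the included
#'   (concordant) panel members.
#' @return 100 * sum(scores) / length(scores).
#' @export
riskPercentile <- function(scores) {
  if (length(scores) == 0) stop("no included biomarkers")
  100 * sum(scores) / length(scores)
}

.oppositeModulation <- function(direction) {
  ifelse(direction == "increased", "decreases", "increases")
}

#' Per-drug percentile match to a patient's digitized biomarker profile
#'
#' The drug table is first restricted to drugs modulating a biomarker's
#' gene opposite to its high-anxiety direction. Each matched biomarker
#' contributes its digitized score; the drug total is normalized by the
#' number of the patient's biomarkers scoring 1 or 0.5.
#'
#' @param scores digitized scores named by gene symbol.
#' @param directions marker directions named by gene symbol.
#' @param drug_table data.frame: drug, gene_symbol, modulation
#'   ("increases"/"decreases").
#' @return named numeric vector of percentiles per drug (NA when the
#'   patient has no biomarker scoring >= 0.5).
#' @export
drugMatchPercentile <- function(scores, directions, drug_table) {
  denom <- sum(scores >= 0.5)
  drugs <- unique(drug_table$drug)
  out <- stats::setNames(rep(NA_real_, length(drugs)), drugs)
  if (denom == 0) return(out)
  for (d in drugs) {
    rows <- drug_table[drug_table$drug == d, , drop = FALSE]
    genes <- intersect(rows$gene_symbol, names(scores))
    genes <- genes[rows$modulation[match(genes, rows$gene_symbol)] ==
                     .oppositeModulation(directions[genes])]
    out[d] <- 100 * sum(scores[genes]) / denom
  }
  out
}

#' Panel-level drug coverage (best existing treatments)
#'
#' Fraction of the panel's unique gene symbols that a drug modulates in
#' the opposite direction to their change in high anxiety.
#'
#' @param panel data.frame with gene_symbol and direction columns
#'   (probeset-level rows allowed; genes are deduplicated).
#' @param drug_table data.frame: drug, gene_symbol, modulation.
#' @return named numeric vector of percentages per drug, sorted decreasing.
#' @export
drugCoverage <- function(panel, drug_table) {
  genes <- panel[!duplicated(panel$gene_symbol), , drop = FALSE]
  if (nrow(genes) == 0) stop("empty panel")
  n <- nrow(genes)
  drugs <- unique(drug_table$drug)
  out <- vapply(drugs, function(d) {
    rows <- drug_table[drug_table$drug == d, , drop = FALSE]
    hit <- vapply(seq_len(n), function(i) {
      any(rows$gene_symbol == genes$gene_symbol[i] &
            rows$modulation == .oppositeModulation(genes$direction[i]))
    }, logical(1))
    100 * sum(hit) / n
  }, numeric(1))
  sort(stats::setNames(out, drugs), decreasing = TRUE)
}

#' Digitized clinician report for one subject
#'
#' Digitizes the subject's most recent visit against three reference
#' threshold sets (anxiety state, first-year hospitalization, all future
#' hospitalizations), computes the three risk percentiles and a combined
#' chronic-risk score (mean of the two hospitalization percentiles), and
#' ranks treatments by percentile match to the state profile.
#'
#' @param z_values named z-scored expression vector for the subject's
#'   visit.
#' @param panel panel data.frame (probeset, gene_symbol, direction).
#' @param thresholds named list of three [referenceThresholds] tables:
#'   state, first_year, all_future.
#' @param drug_table medication modulation table; `nutraceutical_table`
#'   optional alternative-treatment table.
#' @param subject_id label carried into the report.
#' @return list of class "clinicianReport" with per-marker scores,
#'   percentiles, and ranked treatment matches. `writeClinicianReport`
#'   serializes it to JSON and plain text.
#' @export
clinicianReport <- function(z_values, panel, thresholds, drug_table,
                            nutraceutical_table = NULL,
                            subject_id = "subject") {
  per_set <- lapply(thresholds, function(th) {
    th <- th[th$concordant, , drop = FALSE]
    sc <- digitizeBiomarker(z_values[th$probeset], th$high_group_mean,
                            th$low_group_mean, th$direction)
    data.frame(probeset = th$probeset, score = unname(sc),
               stringsAsFactors = FALSE)
  })
  pct <- vapply(per_set, function(s) riskPercentile(s$score), numeric(1))
  chronic <- mean(c(pct[["first_year"]], pct[["all_future"]]))
  state_scores <- per_set[["state"]]
  gene_scores <- stats::setNames(
    state_scores$score,
    panel$gene_symbol[match(state_scores$probeset, panel$probeset)])
  dirs <- stats::setNames(panel$direction, panel$gene_symbol)
  med <- sort(drugMatchPercentile(gene_scores, dirs, drug_table),
              decreasing = TRUE)
  nut <- if (!is.null(nutraceutical_table))
    sort(drugMatchPercentile(gene_scores, dirs, nutraceutical_table),
         decreasing = TRUE) else NULL
  structure(list(
    subject_id = subject_id,
    n_panel = nrow(panel),
    n_concordant = vapply(thresholds, function(th) sum(th$concordant),
                          integer(1)),
    marker_scores = per_set,
    percentiles = list(state = unname(pct[["state"]]),
                       first_year = unname(pct[["first_year"]]),
                       all_future = unname(pct[["all_future"]]),
                       chronic_risk = chronic),
    medication_match = med,
    nutraceutical_match = nut
  ), class = "clinicianReport")
}

#' @describeIn clinicianReport write the report as JSON and plain text.
#' @param report a `clinicianReport`.
#' @param json_path,text_path output paths (either may be NULL).
#' @export
writeClinicianReport <- function(report, json_path = NULL, text_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
  if (!is.null(text_path)) {
    p <- report$percentiles
    lines <- c(
      paste0("Anxiety biomarker panel report - ", report$subject_id),
      sprintf("Panel: %d biomarkers (concordant: state %d, first-year %d, all-future %d)",
              report$n_panel, report$n_concordant[["state"]],
              report$n_concordant[["first_year"]],
              report$n_concordant[["all_future"]]),
      sprintf("Anxiety state risk percentile:        %.1f", p$state),
      sprintf("First-year hospitalization percentile: %.1f", p$first_year),
      sprintf("All-future hospitalization percentile: %.1f", p$all_future),
      sprintf("Combined chronic anxiety risk:         %.1f", p$chronic_risk),
      "Top medication matches:",
      sprintf("  %-30s %.1f", names(report$medication_match),
              report$medication_match)
    )
    if (!is.null(report$nutraceutical_match))
      lines <- c(lines, "Top alternative-treatment matches:",
                 sprintf("  %-30s %.1f", names(report$nutraceutical_match),
                         report$nutraceutical_match))
    writeLines(lines, text_path)
  }
  invisible(report)
}

#' @exportS3Method base::print
print.clinicianReport <- function(x, ...) {
  p <- x$percentiles
  cat("Clinician report for", x$subject_id, "-",
      x$n_panel, "biomarker panel\n")
  cat(sprintf("  state %.1f | first-year %.1f | all-future %.1f | chronic %.1f\n",
              p$state, p$first_year, p$all_future, p$chronic_risk))
  top <- utils::head(x$medication_match, 3)
  cat("  top matches:", paste(sprintf("%s (%.1f)", names(top), top),
                              collapse = ", "), "\n")
  invisible(x)
}
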