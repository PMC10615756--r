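#' Full pipeline configuration
#'
#' Bundles the synthetic-cohort settings with every scoring threshold of
#' the four-step framework. Defaults are the published operating points:
#' state thresholds SAS-4 <= 40 / >= 60 with STAI >= 55 for severity,
#' discovery cuts 33/50/80% mapping to 2/4/6 points, combined
#' discovery+CFG gate 6, CFE3 gate 8, significance level 0.05.
#'
#' @param sim a [cohortSimConfig] (used when no input paths are given).
#' @param expression_path,metadata_path,detection_path optional input
#'   files read via [readCohort] instead of simulating (metadata must then
#'   carry a `cohort` column naming the arm).
#' @param evidence_sensitivity,evidence_fpr synthetic evidence-table rates.
#' @param de_fold_threshold DE log fold-change cutoff.
#' @param gate_combined,gate_cfe3 candidate and top-panel gates.
#' @param alpha significance level.
#' @param validation_max_points 6 or 4 (caps the Bonferroni tier).
#' @param panel_size optional top-panel size.
#' @param strata z-scoring strata columns.
#' @param seed master seed; stage substreams are derived from it.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(sim = cohortSimConfig(),
                           expression_path = NULL, metadata_path = NULL,
                           detection_path = NULL,
                           evidence_sensitivity = 0.8,
                           evidence_fpr = 0.05,
                           de_fold_threshold = 0.263,
                           gate_combined = 6, gate_cfe3 = 8,
                           alpha = 0.05, validation_max_points = 6,
                           panel_size = NULL,
                           strata = c("gender", "diagnosis"),
                           seed = 1L) {
  cfg <- as.list(environment())
  cfg$sim$seed <- as.integer(seed)
  structure(cfg, class = "PipelineConfig")
}

#' Split a multi-arm cohort into discovery / validation / test arms
#'
#' @param cohort an [AnxietyCohort-class] whose visit table has a `cohort`
#'   column with values "discovery", "validation", "test".
#' @return named list of single-arm cohorts.
#' @export
splitArms <- function(cohort) {
  arm <- colData(cohort)$cohort
  if (is.null(arm)) stop("cohort has no 'cohort' arm column")
  lapply(stats::setNames(nm = intersect(.COHORT_ARMS, unique(arm))),
         function(a) cohort[, arm == a])
}

#' Run the four-step biomarker pipeline end to end
#'
#' Simulates (or reads) the three cohort arms, z-scores expression within
#' gender-by-diagnosis strata (the validation arm on the discovery arm's
#' frozen parameters), scores discovery tracking, adds CFG prioritization
#' points, gates candidates, validates against the severe-anxiety arm,
#' tests state/trait prediction in the independent test arm, and composes
#' the CFE scorecard and top panel. All stage outputs are written to
#' `out_dir` as delimited text plus a JSON run manifest; identical
#' configurations produce identical outputs.
#'
#' @param config a [pipelineConfig].
#' @param out_dir output directory (created if needed); NULL to skip
#'   writing files.
#' @param steps run through step `steps` (3 skips predictive testing; the
#'   scorecard then carries only CFE3).
#' @return invisibly, a list with cohort arms, truth, stage tables,
#'   scorecard, panel, and the full-array CFE3 ranking.
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir = NULL,
                        steps = 4) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!is.null(config$expression_path)) {
    full <- readCohort(config$expression_path, config$metadata_path,
                       config$detection_path)
    truth <- NULL
    annotation <- data.frame(probeset = rownames(full),
                             gene_symbol = rownames(full),
                             stringsAsFactors = FALSE)
    evidence <- data.frame(gene_symbol = character(), species = character(),
                           evidence_kind = character(), weight = numeric())
  } else {
    sim <- simulateCohort(config$sim)
    full <- sim$cohort
    truth <- sim$truth
    annotation <- truth$annotation
    evidence <- simulateEvidenceTable(truth,
                                      sensitivity = config$evidence_sensitivity,
                                      false_positive_rate = config$evidence_fpr,
                                      seed = config$seed + 1L)
  }
  arms <- splitArms(full)
  message("cohort arms: ",
          paste(names(arms), vapply(arms, ncol, integer(1)),
                sep = "=", collapse = ", "), " visits")

  disc <- zscoreByStratum(arms$discovery, strata = config$strata)
  vali <- zscoreByStratum(arms$validation, strata = config$strata,
                          params = zscoreParams(disc))
  test <- if (!is.null(arms$test))
    zscoreByStratum(arms$test, strata = config$strata) else NULL

  pairs <- findDiametricPairs(disc)
  message("step 1: ", nrow(pairs), " diametric pairs")
  discovery <- scoreDiscovery(disc, pairs,
                              de_fold_threshold = config$de_fold_threshold)

  cfg_scores <- scoreCFG(discovery, evidence, annotation)
  candidates <- selectCandidates(cfg_scores, gate = config$gate_combined)
  message("step 2: ", nrow(candidates), " candidates at combined >= ",
          config$gate_combined)

  validated <- scoreValidation(disc, vali, candidates,
                               alpha = config$alpha,
                               max_points = config$validation_max_points)
  message("step 3: ", sum(validated$stepwise), " stepwise, ",
          sum(validated$anova_p < config$alpha), " nominally significant")

  # CFE3 ranking over the whole array (non-candidates score no validation)
  ranking <- cfg_scores
  ranking$validation_points <- 0L
  m <- match(validated$probeset, ranking$probeset)
  ranking$validation_points[m] <- validated$validation_points
  ranking$cfe3 <- ranking$combined + ranking$validation_points
  ranking <- ranking[order(-ranking$cfe3, ranking$probeset), , drop = FALSE]
  rownames(ranking) <- NULL

  predictions <- NULL
  scorecard <- validated
  if (steps >= 4 && !is.null(test)) {
    predictions <- testPrediction(test, validated, alpha = config$alpha)
    scorecard <- buildScorecard(validated, predictions, alpha = config$alpha)
    message("step 4: ", nrow(predictions), " stratum-level tests")
  }
  panel <- selectTopPanel(scorecard, gate_cfe3 = config$gate_cfe3,
                          panel_size = config$panel_size)
  message("panel: ", nrow(panel), " biomarkers at CFE3 >= ", config$gate_cfe3)

  res <- list(arms = list(discovery = disc, validation = vali, test = test),
              truth = truth, pairs = pairs, discovery = discovery,
              candidates = candidates, validated = validated,
              predictions = predictions, scorecard = scorecard,
              panel = panel, ranking = ranking, config = config)
  if (!is.null(out_dir)) .writePipelineOutputs(res, out_dir)
  invisible(res)
}

.writePipelineOutputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(res$discovery, "discovery.csv")
  w(res$candidates, "candidates.csv")
  w(res$validated, "validation.csv")
  if (!is.null(res$predictions)) w(res$predictions, "predictions.csv")
  w(res$scorecard, "scorecard.csv")
  w(res$ranking, "ranking.csv")
  jsonlite::write_json(res$panel, file.path(out_dir, "panel.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  cfg <- res$config
  cfg_plain <- rapply(unclass(cfg), identity, how = "replace")
  yaml::write_yaml(cfg_plain, file.path(out_dir, "config.yaml"))
  manifest <- list(
    package = "anxietyCFE",
    version = as.character(utils::packageVersion("anxietyCFE")),
    seed = cfg$seed,
    n_probesets = if (!is.null(res$truth)) length(res$truth$annotation$probeset)
      else nrow(res$arms$discovery),
    n_pairs = nrow(res$pairs),
    n_candidates = nrow(res$candidates),
    n_panel = nrow(res$panel)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
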