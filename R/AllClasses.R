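#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.GENDERS <- c("M", "F")
.DIAGNOSES <- c("BP", "MDD", "SZ", "SZA", "PTSD")
.STATE_LEVELS <- c("LOW", "INTERMEDIATE", "HIGH", "SEVERE")
.COHORT_ARMS <- c("discovery", "validation", "test")

# colData columns every cohort must carry (visit_time in decimal years from
# the subject's first visit; follow-up times measured forward from each visit)
.REQUIRED_VISIT_COLS <- c(
  "subject_id", "visit_index", "gender", "diagnosis", "sas4", "stai_state",
  "followup_first_year_hosp", "followup_any_future_hosp",
  "time_to_first_hosp", "censor_time", "visit_time"
)

#' Cohort container for probeset-by-visit expression with visit phenotypes
#'
#' `AnxietyCohort` extends [SummarizedExperiment::SummarizedExperiment] with
#' a fixed visit-level phenotype schema: subject identity, visit order and
#' time, gender, primary psychiatric diagnosis, the SAS-4 anxiety
#' visual-analog score (0-100), the STAI State score, and
#' hospitalization follow-up outcomes measured forward from each visit.
#' The `"exprs"` assay holds normalized (log-scale) expression values;
#' an optional `"detection"` assay holds logical Present/Absent calls.
#'
#' @slot zscored logical scalar; TRUE after stratified z-scoring.
#' @export
setClass("AnxietyCohort",
  contains = "SummarizedExperiment",
  representation(zscored = "logical"),
  prototype(zscored = FALSE)
)

.validAnxietyCohort <- function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  cd <- colData(object)
  miss <- setdiff(.REQUIRED_VISIT_COLS, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing visit columns: ", paste(miss, collapse = ", ")))
  if (length(msg)) return(msg)
  x <- assay(object, "exprs")
  if (anyDuplicated(rownames(x)))
    msg <- c(msg, "duplicate probeset ids")
  if (anyDuplicated(colnames(x)))
    msg <- c(msg, "duplicate sample ids")
  if (!all(is.finite(x)))
    msg <- c(msg, "non-finite expression values")
  sas4 <- cd$sas4
  if (any(!is.na(sas4) & (sas4 < 0 | sas4 > 100)))
    msg <- c(msg, "sas4 outside [0, 100]")
  if (any(!cd$gender %in% .GENDERS))
    msg <- c(msg, "gender must be 'M' or 'F'")
  if (any(!cd$diagnosis %in% .DIAGNOSES))
    msg <- c(msg, paste0("diagnosis must be one of ", paste(.DIAGNOSES, collapse = ", ")))
  dup <- any(vapply(split(cd$visit_index, cd$subject_id),
                    anyDuplicated, integer(1)) > 0)
  if (dup)
    msg <- c(msg, "visit_index not unique within subject")
  tt <- cd$time_to_first_hosp
  ct <- cd$censor_time
  bad <- !is.na(tt) & !is.na(ct) & tt > ct
  if (any(bad))
    msg <- c(msg, "time_to_first_hosp exceeds censor_time")
  if ("detection" %in% SummarizedExperiment::assayNames(object)) {
    d <- assay(object, "detection")
    if (!is.logical(d) || !identical(dim(d), dim(x)))
      msg <- c(msg, "detection assay must be a logical matrix matching 'exprs'")
  }
  if (length(msg)) msg else TRUE
}
setValidity("AnxietyCohort", .validAnxietyCohort)

#' Construct an AnxietyCohort
#'
#' @param exprs numeric matrix, probesets x samples, with row and column names.
#' @param visits data.frame of visit phenotypes, one row per sample. Must
#'   contain a `sample_id` column matching `colnames(exprs)` plus the
#'   required visit fields (see [AnxietyCohort-class]); `visit_time` is
#'   derived from `visit_index` (half-year spacing) when absent, and missing
#'   follow-up fields are filled with `NA`.
#' @param detection optional logical matrix of Present calls, same shape as
#'   `exprs` (or a character matrix of "P"/"A" flags).
#' @return An [AnxietyCohort-class] object.
#' @export
AnxietyCohort <- function(exprs, visits, detection = NULL) {
  exprs <- as.matrix(exprs)
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("'exprs' must have probeset rownames and sample colnames")
  if (!"sample_id" %in% colnames(visits))
    stop("'visits' must contain a 'sample_id' column")
  extra <- setdiff(visits$sample_id, colnames(exprs))
  if (length(extra))
    stop("metadata sample ids absent from expression matrix: ",
         paste(extra, collapse = ", "))
  extra2 <- setdiff(colnames(exprs), visits$sample_id)
  if (length(extra2))
    stop("expression samples absent from metadata: ",
         paste(extra2, collapse = ", "))
  visits <- visits[match(colnames(exprs), visits$sample_id), , drop = FALSE]
  if (!"visit_time" %in% colnames(visits))
    visits$visit_time <- (visits$visit_index - 1) * 0.5
  for (fld in c("stai_state", "time_to_first_hosp", "censor_time"))
    if (!fld %in% colnames(visits)) visits[[fld]] <- NA_real_
  for (fld in c("followup_first_year_hosp", "followup_any_future_hosp"))
    if (!fld %in% colnames(visits)) visits[[fld]] <- NA
  visits$followup_first_year_hosp <- as.logical(visits$followup_first_year_hosp)
  visits$followup_any_future_hosp <- as.logical(visits$followup_any_future_hosp)
  assays <- list(exprs = exprs)
  if (!is.null(detection)) {
    if (is.character(detection)) detection <- detection == "P"
    mode(detection) <- "logical"
    dimnames(detection) <- dimnames(exprs)
    assays$detection <- detection
  }
  cd <- DataFrame(visits, row.names = visits$sample_id)
  se <- SummarizedExperiment(assays = assays, colData = cd)
  new("AnxietyCohort", se, zscored = FALSE)
}

#' @describeIn AnxietyCohort expression matrix accessor.
#' @param x,object an `AnxietyCohort`.
#' @export
exprsMatrix <- function(x) assay(x, "exprs")

#' @describeIn AnxietyCohort logical Present-call matrix, or NULL.
#' @export
detectionCalls <- function(x) {
  if ("detection" %in% SummarizedExperiment::assayNames(x))
    assay(x, "detection") else NULL
}

#' @describeIn AnxietyCohort visit phenotype table as a base data.frame.
#' @export
visitData <- function(x) as.data.frame(colData(x))

#' @describeIn AnxietyCohort TRUE once expression has been z-scored.
#' @export
isZscored <- function(x) x@zscored

setMethod("show", "AnxietyCohort", function(object) {
  cd <- colData(object)
  cat("AnxietyCohort:", nrow(object), "probesets x", ncol(object), "visits\n")
  cat("  subjects:", length(unique(cd$subject_id)),
      "| z-scored:", object@zscored,
      "| detection calls:",
      "detection" %in% SummarizedExperiment::assayNames(object), "\n")
  if ("cohort" %in% colnames(cd))
    print(table(arm = cd$cohort))
  invisible(NULL)
})
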