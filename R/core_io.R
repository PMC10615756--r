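#' Read an expression + visit-metadata cohort from delimited text files
#'
#' Expression files are TSV or CSV (decided by file extension) with the
#' probeset identifier in the first column and one column per visit sample.
#' Metadata files carry one row per sample with the visit phenotype fields.
#' An optional detection-call file mirrors the expression layout with
#' "P"/"A" flags.
#'
#' @param expression_path path to the expression table.
#' @param metadata_path path to the visit metadata table.
#' @param detection_path optional path to a Present/Absent call table.
#' @return An [AnxietyCohort-class].
#' @export
readCohort <- function(expression_path, metadata_path, detection_path = NULL) {
  expr_df <- .readTable(expression_path)
  meta <- .readTable(metadata_path)
  probesets <- as.character(expr_df[[1]])
  if (anyDuplicated(probesets))
    stop("duplicate probeset ids in ", expression_path, ": ",
         paste(unique(probesets[duplicated(probesets)]), collapse = ", "))
  vals <- expr_df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1) num <- matrix(num, nrow = 1)
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric expression value at probeset '",
         probesets[bad[1, 1]], "', sample '", colnames(vals)[bad[1, 2]], "'")
  if (anyNA(num))
    stop("missing expression values are not supported")
  rownames(num) <- probesets
  colnames(num) <- colnames(vals)
  detection <- NULL
  if (!is.null(detection_path)) {
    det_df <- .readTable(detection_path)
    det <- as.matrix(det_df[, -1, drop = FALSE])
    rownames(det) <- as.character(det_df[[1]])
    if (!identical(dimnames(det), dimnames(num)))
      stop("detection-call file layout does not match the expression file")
    detection <- det
  }
  missing_samples <- setdiff(meta$sample_id, colnames(num))
  if (length(missing_samples))
    stop("metadata sample ids absent from expression header: ",
         paste(missing_samples, collapse = ", "))
  AnxietyCohort(num, meta, detection = detection)
}

#' Write a cohort back to delimited text files
#'
#' Inverse of [readCohort]: `readCohort` on the written files reproduces the
#' cohort's expression values and visit metadata.
#'
#' @param cohort an [AnxietyCohort-class].
#' @param expression_path,metadata_path output paths (TSV or CSV by extension).
#' @param detection_path optional output path for Present/Absent flags.
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(cohort, expression_path, metadata_path,
                        detection_path = NULL) {
  x <- exprsMatrix(cohort)
  expr_df <- data.frame(probeset = rownames(x), x, check.names = FALSE)
  .writeTable(expr_df, expression_path)
  .writeTable(visitData(cohort), metadata_path)
  d <- detectionCalls(cohort)
  if (!is.null(detection_path) && !is.null(d)) {
    flags <- ifelse(d, "P", "A")
    .writeTable(data.frame(probeset = rownames(x), flags, check.names = FALSE),
                detection_path)
  }
  invisible(c(expression_path, metadata_path))
}

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

.writeTable <- function(df, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Label the anxiety state of visits from SAS-4 and STAI State scores
#'
#' Thresholds follow the clinical definitions: LOW is SAS-4 <= 40, a visit
#' with SAS-4 >= 60 is HIGH, and HIGH visits with a concordant STAI State
#' score >= 55 are SEVERE (clinically severe anxiety). Anything in between
#' is INTERMEDIATE. A HIGH visit with a missing STAI score is never SEVERE.
#'
#' @param sas4 numeric vector of SAS-4 scores (0-100), no missing values.
#' @param stai_state numeric vector of STAI State scores, NA allowed.
#' @param low,high,severe_stai the three thresholds (inclusive).
#' @return factor with levels LOW, INTERMEDIATE, HIGH, SEVERE.
#' @export
labelState <- function(sas4, stai_state = NA_real_,
                       low = 40, high = 60, severe_stai = 55) {
  if (anyNA(sas4)) stop("sas4 must not be missing")
  stai_state <- rep_len(stai_state, length(sas4))
  out <- rep("INTERMEDIATE", length(sas4))
  out[sas4 <= low] <- "LOW"
  is_high <- sas4 >= high
  out[is_high] <- "HIGH"
  out[is_high & !is.na(stai_state) & stai_state >= severe_stai] <- "SEVERE"
  factor(out, levels = .STATE_LEVELS)
}

#' @describeIn labelState state labels for every visit of a cohort.
#' @param cohort an [AnxietyCohort-class].
#' @export
stateLabels <- function(cohort, low = 40, high = 60, severe_stai = 55) {
  cd <- colData(cohort)
  labelState(cd$sas4, cd$stai_state, low = low, high = high,
             severe_stai = severe_stai)
}

#' Z-score expression within gender-by-diagnosis strata
#'
#' Expression is normalized for biological variability by z-scoring each
#' probeset within each stratum (gender x primary diagnosis by default)
#' before strata are combined: within a stratum every probeset ends with
#' sample mean 0 and sample standard deviation 1 (n - 1 denominator).
#' Zero-variance probesets within a stratum are set to 0 with a warning.
#'
#' When `params` (from a previous call's `zscoreParams`) is supplied, the
#' stored stratum means and SDs are applied instead of re-estimating them,
#' so an independent cohort can be placed on a reference cohort's scale;
#' strata absent from `params` fall back to their own estimates with a
#' warning.
#'
#' @param cohort an [AnxietyCohort-class].
#' @param strata character vector of visit columns defining the strata.
#' @param params optional frozen normalization parameters.
#' @return The cohort with z-scored `exprs`; `zscoreParams()` recovers the
#'   per-stratum means/SDs.
#' @export
zscoreByStratum <- function(cohort, strata = c("gender", "diagnosis"),
                            params = NULL) {
  cd <- as.data.frame(colData(cohort))
  key <- interaction(cd[strata], drop = TRUE, sep = ".")
  x <- exprsMatrix(cohort)
  out <- x
  est <- list()
  zero_var <- FALSE
  for (lev in levels(key)) {
    idx <- which(key == lev)
    if (is.null(params) || is.null(params[[lev]])) {
      if (length(idx) < 2)
        stop("stratum '", lev, "' has fewer than 2 samples")
      if (!is.null(params))
        warning("stratum '", lev, "' absent from frozen parameters; ",
                "using its own estimates")
      m <- rowMeans(x[, idx, drop = FALSE])
      s <- apply(x[, idx, drop = FALSE], 1, stats::sd)
    } else {
      m <- params[[lev]]$mean
      s <- params[[lev]]$sd
    }
    z <- (x[, idx, drop = FALSE] - m) / s
    if (any(s == 0)) {
      zero_var <- TRUE
      z[s == 0, ] <- 0
    }
    out[, idx] <- z
    est[[lev]] <- list(mean = m, sd = s)
  }
  if (zero_var)
    warning("zero-variance probesets within a stratum were set to 0")
  res <- cohort
  SummarizedExperiment::assay(res, "exprs") <- out
  res@zscored <- TRUE
  metadata(res)$zscore_params <- est
  metadata(res)$zscore_strata <- strata
  res
}

#' @describeIn zscoreByStratum retrieve frozen per-stratum means and SDs.
#' @export
zscoreParams <- function(cohort) metadata(cohort)$zscore_params
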