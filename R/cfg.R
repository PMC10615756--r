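.CFG_KINDS <- c("genetic", "expression_brain", "expression_peripheral",
                "protein")

#' Default Convergent Functional Genomics category scheme
#'
#' Six evidence categories -- human and animal-model versions of genetic,
#' brain-expression, and peripheral-expression evidence -- each capped at
#' 2 points, reconstructing the published maximum of 12 CFG points.
#' Protein evidence folds into the expression category of its tissue.
#'
#' @param category_cap per-category cap (default 2).
#' @param total_cap overall CFG cap (default 12).
#' @return list with `categories`, `category_cap`, `total_cap`.
#' @export
cfgDefaultScheme <- function(category_cap = 2, total_cap = 12) {
  list(categories = as.vector(outer(c("human", "animal"),
                                    c("genetic", "brain", "peripheral"),
                                    paste, sep = "_")),
       category_cap = category_cap, total_cap = total_cap)
}

.cfgCategory <- function(species, evidence_kind, tissue = NULL) {
  ok <- evidence_kind %in% .CFG_KINDS
  if (!all(ok))
    stop("unknown evidence_kind: ",
         paste(unique(evidence_kind[!ok]), collapse = ", "))
  slot <- ifelse(evidence_kind == "genetic", "genetic",
          ifelse(evidence_kind == "expression_brain", "brain",
          ifelse(evidence_kind == "expression_peripheral", "peripheral",
                 ifelse(is.null(tissue) | is.na(tissue) | tissue != "brain",
                        "peripheral", "brain"))))
  paste(species, slot, sep = "_")
}

#' Convergent Functional Genomics score for one gene
#'
#' Sums literature evidence weights per category, caps each category, and
#' caps the total at 12 points by default.
#'
#' @param gene_symbol gene to score.
#' @param evidence data.frame with columns gene_symbol, species
#'   ("human"/"animal"), evidence_kind ("genetic", "expression_brain",
#'   "expression_peripheral", "protein"), weight, and optionally tissue
#'   ("brain"/"peripheral") for protein rows.
#' @param scheme a [cfgDefaultScheme] list.
#' @return CFG score in `[0, total_cap]`.
#' @export
cfgScore <- function(gene_symbol, evidence, scheme = cfgDefaultScheme()) {
  rows <- evidence[evidence$gene_symbol == gene_symbol, , drop = FALSE]
  if (nrow(rows) == 0) return(0)
  tissue <- if ("tissue" %in% colnames(rows)) rows$tissue else rep(NA, nrow(rows))
  cat <- .cfgCategory(rows$species, rows$evidence_kind, tissue)
  unknown <- setdiff(cat, scheme$categories)
  if (length(unknown))
    stop("evidence maps outside the category scheme: ",
         paste(unknown, collapse = ", "))
  per_cat <- tapply(rows$weight, cat, sum)
  min(sum(pmin(per_cat, scheme$category_cap)), scheme$total_cap)
}

#' Step 2: CFG points for every scored probeset, and candidate gating
#'
#' Maps probesets to gene symbols, attaches CFG points (0 for probesets
#' without a symbol or without evidence), and combines with discovery
#' points. Where a probeset carries several discovery rows (DE and AP),
#' the maximum internal points is kept and the winning method's direction
#' is retained.
#'
#' @param discovery output of [scoreDiscovery].
#' @param evidence CFG evidence table (see [cfgScore]).
#' @param annotation data.frame probeset -> gene_symbol.
#' @param scheme a [cfgDefaultScheme].
#' @return data.frame: probeset, gene_symbol, method, direction,
#'   percent_of_max, discovery_points, cfg_points, combined.
#' @export
scoreCFG <- function(discovery, evidence, annotation,
                     scheme = cfgDefaultScheme()) {
  ord <- order(discovery$probeset, -discovery$internal_points,
               -discovery$percent_of_max)
  best <- discovery[ord, , drop = FALSE]
  best <- best[!duplicated(best$probeset), , drop = FALSE]
  best$gene_symbol <- annotation$gene_symbol[
    match(best$probeset, annotation$probeset)]
  genes <- unique(best$gene_symbol[!is.na(best$gene_symbol)])
  gscore <- vapply(genes, cfgScore, numeric(1),
                   evidence = evidence, scheme = scheme)
  best$cfg_points <- ifelse(is.na(best$gene_symbol), 0,
                            gscore[best$gene_symbol])
  best$cfg_points[is.na(best$cfg_points)] <- 0
  best$discovery_points <- best$internal_points
  best$combined <- best$discovery_points + best$cfg_points
  rownames(best) <- NULL
  best[, c("probeset", "gene_symbol", "method", "direction",
           "percent_of_max", "discovery_points", "cfg_points", "combined")]
}

#' Gate candidates on the combined discovery + CFG score
#'
#' Keeps probesets whose combined internal and external score is at least
#' `gate` (default 6 of a possible 18), sorted by combined score
#' descending, ties by probeset id.
#'
#' @param scores output of [scoreCFG].
#' @param gate inclusive combined-score cutoff.
#' @return the gated, sorted subset of `scores`.
#' @export
selectCandidates <- function(scores, gate = 6) {
  stopifnot(gate >= 0)
  keep <- scores[scores$combined >= gate, , drop = FALSE]
  keep <- keep[order(-keep$combined, keep$probeset), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}
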