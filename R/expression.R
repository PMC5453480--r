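#' Load a condition-labelled expression matrix from TSV files
#'
#' The matrix TSV has entity ids in the first column and one column per
#' sample, with a header row of sample ids. The condition map TSV has two
#' columns, `sample_id<TAB>condition`, with condition `normal` or `tumor`.
#' Every matrix sample must be present in the map; values must be
#' non-negative; entity ids must be unique.
#'
#' @param matrixPath path to the expression TSV.
#' @param conditionPath path to the sample-condition TSV.
#' @return a [ConditionedExpression-class].
#' @export
loadExpression <- function(matrixPath, conditionPath) {
  if (!file.exists(matrixPath)) stop("cannot read expression: ", matrixPath)
  if (!file.exists(conditionPath))
    stop("cannot read condition map: ", conditionPath)
  d <- read.table(matrixPath, sep = "\t", header = TRUE, check.names = FALSE,
                  comment.char = "")
  ids <- normalizeId(d[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated entity id(s) in ", matrixPath, ": ",
         paste(unique(ids[duplicated(ids)])[1:3], collapse = ", "))
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyNA(m)) stop("non-numeric or missing expression values")
  if (any(m < 0)) stop("negative expression values in ", matrixPath)
  cm <- read.table(conditionPath, sep = "\t", header = FALSE,
                   col.names = c("sample_id", "condition"),
                   colClasses = "character", comment.char = "#")
  cond <- stats::setNames(trimws(cm$condition), trimws(cm$sample_id))
  bad <- setdiff(unique(cond), CONDITIONS)
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  ConditionedExpression(m, cond)
}

#' Fold-change differential expression
#'
#' For each entity, computes the arithmetic mean over the normal and tumor
#' samples and
#' `log2_fc = log2((mean_tumor + pseudocount) / (mean_normal + pseudocount))`.
#' The pseudocount keeps zero-expression entities finite; on an RPKM-like
#' scale the default 0.01 is negligible for expressed entities.
#'
#' @param expr a [ConditionedExpression-class] with >= 1 sample per condition.
#' @param pseudocount positive stabilizer added to both means.
#' @param threshold selection cutoff on `|log2_fc|` (strict; the
#'   conventional fold-change-2 rule).
#' @return data.frame with columns `entity_id`, `mean_normal`, `mean_tumor`,
#'   `log2_fc`, `selected`.
#' @export
computeLog2FoldChange <- function(expr, pseudocount = 0.01, threshold = 1) {
  stopifnot(is(expr, "ConditionedExpression"))
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  cond <- sampleCondition(expr)
  if (!all(CONDITIONS %in% cond))
    stop("both a normal and a tumor condition are required")
  v <- exprValues(expr)
  mn <- rowMeans(v[, cond == "normal", drop = FALSE])
  mt <- rowMeans(v[, cond == "tumor", drop = FALSE])
  lfc <- log2((mt + pseudocount) / (mn + pseudocount))
  data.frame(entity_id = rownames(v),
             mean_normal = unname(mn), mean_tumor = unname(mt),
             log2_fc = unname(lfc),
             selected = unname(abs(lfc) > threshold),
             stringsAsFactors = FALSE)
}

#' Select differentially expressed entities
#'
#' Returns entity ids with `|log2_fc|` strictly greater than the threshold
#' (fold change > 2 or < 0.5 at the default threshold of 1).
#'
#' @param deTable data.frame from [computeLog2FoldChange()].
#' @param threshold strict cutoff on `|log2_fc|`, must be > 0.
#' @return character vector of selected entity ids.
#' @export
selectDifferential <- function(deTable, threshold = 1) {
  if (threshold <= 0) stop("threshold must be > 0")
  deTable$entity_id[abs(deTable$log2_fc) > threshold]
}
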