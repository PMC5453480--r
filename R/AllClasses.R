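#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

CONDITIONS <- c("normal", "tumor")

#' Condition-labelled expression matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay of
#' non-negative, RPKM-like abundance values (entities in rows, samples in
#' columns) together with a mandatory `condition` column in `colData`
#' labelling every sample as `"normal"` or `"tumor"`.
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#' @seealso [ConditionedExpression()], [sampleCondition()], [exprValues()]
#' @export
setClass("ConditionedExpression", contains = "SummarizedExperiment")

setValidity("ConditionedExpression", function(object) {
  msg <- character()
  if (!"condition" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'condition' column")
  else {
    cond <- as.character(colData(object)$condition)
    bad <- setdiff(unique(cond), CONDITIONS)
    if (length(bad))
      msg <- c(msg, paste0("unknown condition label(s): ",
                           paste(bad, collapse = ", ")))
  }
  if (length(SummarizedExperiment::assays(object)) < 1L)
    msg <- c(msg, "exactly one assay of expression values is required")
  else {
    v <- assay(object, 1L)
    if (anyNA(v)) msg <- c(msg, "expression values must not be NA")
    else if (any(v < 0)) msg <- c(msg, "negative expression values are not allowed")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated entity ids")
  if (length(msg)) msg else TRUE
})

#' Construct a ConditionedExpression object
#'
#' @param values numeric matrix, entities x samples, with row and column
#'   names; all values must be finite and non-negative.
#' @param condition character vector of `"normal"`/`"tumor"` labels, either
#'   named by sample id or given in column order of `values`.
#' @return A [ConditionedExpression-class] object.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' ce <- ConditionedExpression(m, c(s1 = "normal", s2 = "tumor", s3 = "tumor"))
#' sampleCondition(ce)
#' @export
ConditionedExpression <- function(values, condition) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have entity rownames and sample colnames")
  if (!is.null(names(condition))) {
    missing <- setdiff(colnames(values), names(condition))
    if (length(missing))
      stop("sample(s) missing from the condition map: ",
           paste(missing, collapse = ", "))
    condition <- condition[colnames(values)]
  } else if (length(condition) != ncol(values)) {
    stop("condition must be named or match the number of samples")
  }
  new("ConditionedExpression",
      SummarizedExperiment(
        assays  = SimpleList(expr = values),
        colData = DataFrame(condition = as.character(condition),
                            row.names = colnames(values))))
}

#' @describeIn ConditionedExpression sample condition labels, named by sample.
#' @param object,x a `ConditionedExpression`
#' @export
sampleCondition <- function(x) {
  stats::setNames(as.character(colData(x)$condition), colnames(x))
}

#' @describeIn ConditionedExpression the expression matrix; optionally
#'   restricted to the samples of one condition.
#' @param condition optional, `"normal"` or `"tumor"`.
#' @export
exprValues <- function(x, condition = NULL) {
  v <- assay(x, 1L)
  if (!is.null(condition)) {
    condition <- match.arg(condition, CONDITIONS)
    v <- v[, sampleCondition(x) == condition, drop = FALSE]
  }
  v
}

#' Single-source miRNA-target prediction table
#'
#' Holds the deduplicated (miRNA, gene) pairs predicted by one source
#' database. Identifiers are lower-cased and whitespace-stripped on load so
#' that all sources share one namespace.
#'
#' @slot sourceName single string naming the prediction source.
#' @slot pairs data.frame with character columns `mirna` and `gene`;
#'   no duplicated pairs, no empty identifiers.
#' @export
setClass("PredictionTable",
         representation(sourceName = "character", pairs = "data.frame"))

setValidity("PredictionTable", function(object) {
  msg <- character()
  if (length(object@sourceName) != 1L || !nzchar(object@sourceName))
    msg <- c(msg, "sourceName must be a single non-empty string")
  p <- object@pairs
  if (!all(c("mirna", "gene") %in% colnames(p)))
    msg <- c(msg, "pairs must have 'mirna' and 'gene' columns")
  else {
    if (nrow(p) && (!all(nzchar(p$mirna)) || !all(nzchar(p$gene))))
      msg <- c(msg, "empty identifiers in pairs")
    if (anyDuplicated(paste(p$mirna, p$gene, sep = "\r")))
      msg <- c(msg, "duplicated pairs within one source")
  }
  if (length(msg)) msg else TRUE
})

PredictionTable <- function(sourceName, mirna, gene) {
  pairs <- unique(data.frame(mirna = as.character(mirna),
                             gene = as.character(gene),
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  new("PredictionTable", sourceName = sourceName, pairs = pairs)
}

#' Consensus miRNA-target interaction catalog
#'
#' Candidate interactions retained because they are predicted by at least
#' `minSources` distinct sources. One record per (miRNA, gene) pair.
#'
#' @slot records data.frame with columns `mirna`, `gene`,
#'   `source_count` (integer) and `sources` (comma-joined source names).
#' @slot minSources the consensus threshold used to build the catalog.
#' @seealso [buildCatalog()]
#' @export
setClass("InteractionCatalog",
         representation(records = "data.frame", minSources = "integer"))

setValidity("InteractionCatalog", function(object) {
  r <- object@records
  msg <- character()
  need <- c("mirna", "gene", "source_count", "sources")
  if (!all(need %in% colnames(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(r)) {
    if (anyDuplicated(paste(r$mirna, r$gene, sep = "\r")))
      msg <- c(msg, "(mirna, gene) pairs must be unique")
    nsrc <- lengths(strsplit(r$sources, ",", fixed = TRUE))
    if (!all(nsrc == r$source_count))
      msg <- c(msg, "source_count must equal the number of listed sources")
    if (any(r$source_count < 1L))
      msg <- c(msg, "source_count must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Per-condition negative-correlation regulatory network
#'
#' Bipartite miRNA-gene network for one condition: an edge is retained when
#' the Pearson correlation of the pair over that condition's samples is
#' strictly negative. The full table of raw (unfiltered) correlations is kept
#' alongside so that the differential network can look up the out-of-network
#' side of a pair.
#'
#' @slot condition `"normal"` or `"tumor"`.
#' @slot edges data.frame (`mirna`, `gene`, `pcc`), all `pcc < 0`.
#' @slot rawCorrelations data.frame (`mirna`, `gene`, `pcc`) over every
#'   eligible catalog pair with a defined correlation, before the sign filter.
#' @slot nSkipped number of pairs dropped for undefined correlation
#'   (zero variance) or unmeasured entities.
#' @seealso [buildConditionNetwork()]
#' @export
setClass("ConditionNetwork",
         representation(condition = "character", edges = "data.frame",
                        rawCorrelations = "data.frame", nSkipped = "integer"))

setValidity("ConditionNetwork", function(object) {
  msg <- character()
  if (!object@condition %in% CONDITIONS)
    msg <- c(msg, "condition must be 'normal' or 'tumor'")
  e <- object@edges
  if (!all(c("mirna", "gene", "pcc") %in% colnames(e)))
    msg <- c(msg, "edges must have columns mirna, gene, pcc")
  else if (nrow(e) && !all(e$pcc < 0 & e$pcc >= -1))
    msg <- c(msg, "edge pcc values must lie in [-1, 0)")
  if (length(msg)) msg else TRUE
})

#' miRNA-gene differential regulatory network (MGDRN)
#'
#' Bipartite differential network between the tumor and normal
#' negative-correlation networks. Each edge carries the raw per-condition
#' correlations, their signed difference `delta = pcc_tumor - pcc_normal`
#' (strictly exceeding the difference threshold in absolute value) and a
#' dysregulation `direction`: `"up"` when the negative regulation weakens in
#' tumor (`delta > 0`), `"down"` when it strengthens.
#'
#' @slot edges data.frame (`mirna`, `gene`, `pcc_normal`, `pcc_tumor`,
#'   `delta`, `direction`).
#' @slot nodes data.frame (`id`, `type` in mirna/gene, `log2_fc`); only
#'   non-isolated nodes are kept.
#' @slot deltaThreshold the difference threshold used.
#' @seealso [buildMGDRN()]
#' @export
setClass("MGDRN",
         representation(edges = "data.frame", nodes = "data.frame",
                        deltaThreshold = "numeric"))

setValidity("MGDRN", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("mirna", "gene", "pcc_normal", "pcc_tumor", "delta", "direction")
  if (!all(need %in% colnames(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (max(abs(e$delta - (e$pcc_tumor - e$pcc_normal))) > 1e-12)
      msg <- c(msg, "delta must equal pcc_tumor - pcc_normal")
    if (!all(abs(e$delta) > object@deltaThreshold))
      msg <- c(msg, "all |delta| must strictly exceed the threshold")
    if (!all(e$direction == ifelse(e$delta > 0, "up", "down")))
      msg <- c(msg, "direction must be 'up' iff delta > 0")
    ids <- unique(c(e$mirna, e$gene))
    if (!setequal(ids, object@nodes$id))
      msg <- c(msg, "nodes must be exactly the non-isolated edge endpoints")
  }
  if (length(msg)) msg else TRUE
})

#' Pathway gene-set collection (GMT)
#'
#' @slot sets named list of character gene-id vectors; names are pathway ids.
#' @slot descriptions named character vector, parallel to `sets`.
#' @seealso [loadGMT()]
#' @export
setClass("PathwayCollection",
         representation(sets = "list", descriptions = "character"))

setValidity("PathwayCollection", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "pathway ids must be unique and non-NULL")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "empty pathway gene sets are not allowed")
  if (length(msg)) msg else TRUE
})

#' Significance matrix of miRNA x pathway enrichment
#'
#' Entries are `-log10(p)` where the per-cell hypergeometric enrichment p is
#' below `alpha`, and 0 otherwise. Rows (miRNAs) and columns (pathways) with
#' no significant cell are dropped.
#'
#' @slot scores numeric matrix, miRNAs x pathways.
#' @slot alpha the significance level applied per cell.
#' @seealso [significanceMatrix()], [biclusterModules()]
#' @export
setClass("SignificanceMatrix",
         representation(scores = "matrix", alpha = "numeric"))

setValidity("SignificanceMatrix", function(object) {
  if (length(object@scores) && any(object@scores < 0))
    "scores must be non-negative" else TRUE
})

#' A synergy module: miRNAs jointly dysregulating a set of pathways
#'
#' @slot mirnas character set of miRNA ids (>= 2).
#' @slot pathways character set of pathway ids (>= 2).
#' @slot density fraction of significant (nonzero) cells in the
#'   corresponding significance-matrix block.
#' @seealso [biclusterModules()]
#' @export
setClass("SynergyModule",
         representation(mirnas = "character", pathways = "character",
                        density = "numeric"))

setValidity("SynergyModule", function(object) {
  msg <- character()
  if (length(object@mirnas) < 2L) msg <- c(msg, "need >= 2 miRNAs")
  if (length(object@pathways) < 2L) msg <- c(msg, "need >= 2 pathways")
  if (object@density < 0 || object@density > 1)
    msg <- c(msg, "density must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic dataset
#'
#' @slot trueEdges data.frame (`mirna`, `gene`, `pcc_normal`, `pcc_tumor`) of
#'   planted regulatory couplings (target raw-scale correlations).
#' @slot dysregulatedEdges subset of `trueEdges` whose coupling is attenuated
#'   in tumor.
#' @slot deGenes data.frame (`gene`, `log2_fc`) of genes given a tumor mean
#'   shift.
#' @slot moduleTruth list of `list(mirnas=, pathways=)` planted synergy
#'   blocks.
#' @seealso [simulateDataset()]
#' @export
setClass("SyntheticTruth",
         representation(trueEdges = "data.frame",
                        dysregulatedEdges = "data.frame",
                        deGenes = "data.frame",
                        moduleTruth = "list"))

setValidity("SyntheticTruth", function(object) {
  key <- function(d) paste(d$mirna, d$gene, sep = "\r")
  if (!all(key(object@dysregulatedEdges) %in% key(object@trueEdges)))
    "dysregulated edges must be a subset of true edges" else TRUE
})

# -- show methods --------------------------------------------------------

setMethod("show", "PredictionTable", function(object) {
  cat("PredictionTable '", object@sourceName, "': ",
      nrow(object@pairs), " pairs\n", sep = "")
})

setMethod("show", "InteractionCatalog", function(object) {
  r <- object@records
  cat("InteractionCatalog: ", nrow(r), " consensus pairs (minSources = ",
      object@minSources, ")\n", sep = "")
  if (nrow(r))
    cat("  ", length(unique(r$mirna)), " miRNAs, ",
        length(unique(r$gene)), " genes\n", sep = "")
})

setMethod("show", "ConditionNetwork", function(object) {
  cat("ConditionNetwork (", object@condition, "): ", nrow(object@edges),
      " negative-PCC edges of ", nrow(object@rawCorrelations),
      " correlated pairs (", object@nSkipped, " skipped)\n", sep = "")
})

setMethod("show", "MGDRN", function(object) {
  e <- object@edges
  cat("MGDRN: ", nrow(e), " differential edges (",
      sum(e$direction == "up"), " up, ", sum(e$direction == "down"),
      " down) between ", sum(object@nodes$type == "mirna"), " miRNAs and ",
      sum(object@nodes$type == "gene"), " genes; |delta| > ",
      object@deltaThreshold, "\n", sep = "")
})

setMethod("show", "PathwayCollection", function(object) {
  cat("PathwayCollection: ", length(object@sets), " pathways, ",
      length(unique(unlist(object@sets))), " distinct genes\n", sep = "")
})

setMethod("show", "SignificanceMatrix", function(object) {
  cat("SignificanceMatrix: ", nrow(object@scores), " miRNAs x ",
      ncol(object@scores), " pathways, alpha = ", object@alpha, "; ",
      sum(object@scores > 0), " significant cells\n", sep = "")
})

setMethod("show", "SynergyModule", function(object) {
  cat("SynergyModule: ", length(object@mirnas), " miRNAs x ",
      length(object@pathways), " pathways, density ",
      round(object@density, 3), "\n", sep = "")
})

# -- simple accessors ----------------------------------------------------

#' Catalog records as a data.frame
#' @param x an `InteractionCatalog`
#' @export
catalogRecords <- function(x) x@records

#' Edge table of a network object
#' @param x a `ConditionNetwork` or `MGDRN`
#' @export
networkEdges <- function(x) x@edges

#' Node table of an MGDRN
#' @param x an `MGDRN`
#' @export
networkNodes <- function(x) x@nodes

#' Pathway gene sets as a named list
#' @param x a `PathwayCollection`
#' @export
pathwaySets <- function(x) x@sets

#' Score matrix of a SignificanceMatrix
#' @param x a `SignificanceMatrix`
#' @export
scoreMatrix <- function(x) x@scores

#' Member miRNAs of a synergy module
#' @param x a `SynergyModule`
#' @export
moduleMirnas <- function(x) x@mirnas

#' Member pathways of a synergy module
#' @param x a `SynergyModule`
#' @export
modulePathways <- function(x) x@pathways

#' Significant-cell density of a synergy module
#' @param x a `SynergyModule`
#' @export
moduleDensity <- function(x) x@density
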