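#' Pearson's correlation coefficient
#'
#' Plain product-moment correlation between two equal-length numeric
#' vectors, `sum((x - xbar) * (y - ybar)) / sqrt(sum((x - xbar)^2) *
#' sum((y - ybar)^2))`. Returns `NA` when either vector has zero variance
#' (the caller decides how to treat undefined correlations).
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return correlation in `[-1, 1]`, or `NA_real_` if undefined.
#' @examples
#' pearsonCorrelation(c(1, 2, 3), c(3, 2, 1))  # -1
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Correlations for all catalog pairs whose gene is DE-selected and whose
# entities are measured, over the samples of one condition. Returns the raw
# (sign-unfiltered) table plus the count of skipped pairs.
rawCorrelationTable <- function(exprGenes, exprMirnas, catalog, deGenes,
                                condition) {
  condition <- match.arg(condition, CONDITIONS)
  if (!identical(sort(colnames(exprGenes)), sort(colnames(exprMirnas))))
    stop("gene and miRNA matrices must share the same sample set")
  condG <- sampleCondition(exprGenes)
  if (!identical(condG[colnames(exprMirnas)], sampleCondition(exprMirnas)))
    stop("gene and miRNA matrices must share condition labels")
  samples <- names(condG)[condG == condition]
  if (length(samples) < 3L)
    stop("need >= 3 samples in condition '", condition, "'")
  rec <- catalogRecords(catalog)
  keep <- rec$gene %in% deGenes &
    rec$gene %in% rownames(exprGenes) &
    rec$mirna %in% rownames(exprMirnas)
  rec <- rec[keep, c("mirna", "gene"), drop = FALSE]
  nSkipped <- 0L
  if (!nrow(rec))
    return(list(table = data.frame(mirna = character(), gene = character(),
                                   pcc = numeric()),
                nSkipped = nSkipped))
  gm <- exprValues(exprGenes)[unique(rec$gene), samples, drop = FALSE]
  mm <- exprValues(exprMirnas)[unique(rec$mirna), samples, drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(mm), t(gm)))
  pcc <- cc[cbind(match(rec$mirna, rownames(cc)),
                  match(rec$gene, colnames(cc)))]
  undef <- is.na(pcc)
  nSkipped <- sum(undef)
  tab <- data.frame(mirna = rec$mirna[!undef], gene = rec$gene[!undef],
                    pcc = pcc[!undef], stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, nSkipped = nSkipped)
}

#' Build a per-condition negative-correlation regulatory network
#'
#' For every catalog pair whose gene passed the differential-expression
#' filter and whose miRNA and gene are both measured, the Pearson
#' correlation is computed over the requested condition's samples only.
#' Edges with strictly negative correlation are retained (miRNAs are assumed
#' to repress their targets); pairs with undefined correlation (zero
#' variance) are skipped and counted.
#'
#' @param exprGenes,exprMirnas [ConditionedExpression-class] objects sharing
#'   the same samples and condition labels, with >= 3 samples in `condition`.
#' @param catalog an [InteractionCatalog-class].
#' @param deGenes character vector of selected gene ids.
#' @param condition `"normal"` or `"tumor"`.
#' @return a [ConditionNetwork-class].
#' @export
buildConditionNetwork <- function(exprGenes, exprMirnas, catalog, deGenes,
                                  condition) {
  raw <- rawCorrelationTable(exprGenes, exprMirnas, catalog, deGenes,
                             condition)
  edges <- raw$table[raw$table$pcc < 0, , drop = FALSE]
  rownames(edges) <- NULL
  if (!nrow(edges))
    warning("no negative-correlation edges in condition '", condition, "'",
            call. = FALSE)
  new("ConditionNetwork", condition = match.arg(condition, CONDITIONS),
      edges = edges, rawCorrelations = raw$table,
      nSkipped = as.integer(raw$nSkipped))
}

#' Build the differential regulatory network (MGDRN)
#'
#' A pair is eligible when it carries a negative-correlation edge in at
#' least one of the two condition networks; the other condition's raw
#' (sign-unfiltered) correlation is looked up from that network's
#' correlation table. The pair becomes a differential edge when the
#' correlation difference strictly exceeds `deltaThreshold`. With
#' `deltaMode = "signed"` (default) the difference is
#' `delta = pcc_tumor - pcc_normal`; `deltaMode = "absolute"` instead gates
#' on `||pcc_tumor| - |pcc_normal||`. In both modes the reported `delta` is
#' the signed difference and `direction` is `"up"` when `delta > 0`
#' (negative regulation weakened in tumor) and `"down"` otherwise. Pairs
#' whose out-of-network correlation is undefined are skipped. Nodes are
#' annotated with `log2_fc` from the differential-expression table; isolated
#' nodes are dropped.
#'
#' @param netNormal,netTumor [ConditionNetwork-class] objects built from the
#'   same catalog and DE gene set.
#' @param deTable data.frame from [computeLog2FoldChange()] (gene table;
#'   optionally rbind a miRNA table to annotate miRNA nodes too).
#' @param deltaThreshold strict cutoff on the correlation difference.
#' @param deltaMode `"signed"` or `"absolute"`; see Details.
#' @return an [MGDRN-class].
#' @export
buildMGDRN <- function(netNormal, netTumor, deTable = NULL,
                       deltaThreshold = 0.2,
                       deltaMode = c("signed", "absolute")) {
  deltaMode <- match.arg(deltaMode)
  stopifnot(is(netNormal, "ConditionNetwork"),
            is(netTumor, "ConditionNetwork"))
  if (netNormal@condition != "normal" || netTumor@condition != "tumor")
    stop("pass the normal-condition network first, the tumor one second")
  rawN <- netNormal@rawCorrelations
  rawT <- netTumor@rawCorrelations
  eligible <- unique(rbind(netNormal@edges[c("mirna", "gene")],
                           netTumor@edges[c("mirna", "gene")]))
  keyN <- pairKey(rawN$mirna, rawN$gene)
  keyT <- pairKey(rawT$mirna, rawT$gene)
  keyE <- pairKey(eligible$mirna, eligible$gene)
  pccN <- rawN$pcc[match(keyE, keyN)]
  pccT <- rawT$pcc[match(keyE, keyT)]
  defined <- !is.na(pccN) & !is.na(pccT)
  if (any(!defined))
    message(sum(!defined), " pair(s) skipped: correlation undefined in the ",
            "other condition")
  delta <- pccT - pccN
  gate <- if (deltaMode == "signed") abs(delta)
          else abs(abs(pccT) - abs(pccN))
  keep <- defined & gate > deltaThreshold
  edges <- data.frame(mirna = eligible$mirna[keep],
                      gene = eligible$gene[keep],
                      pcc_normal = pccN[keep], pcc_tumor = pccT[keep],
                      delta = delta[keep],
                      direction = as.character(ifelse(delta[keep] > 0,
                                                      "up", "down")),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  ids <- c(sort(unique(edges$mirna)), sort(unique(edges$gene)))
  nodes <- data.frame(id = ids,
                      type = rep(c("mirna", "gene"),
                                 c(length(unique(edges$mirna)),
                                   length(unique(edges$gene)))),
                      log2_fc = rep(NA_real_, length(ids)),
                      stringsAsFactors = FALSE)
  if (!is.null(deTable))
    nodes$log2_fc <- deTable$log2_fc[match(nodes$id, deTable$entity_id)]
  new("MGDRN", edges = edges, nodes = nodes,
      deltaThreshold = deltaThreshold)
}

#' Convert an MGDRN to an undirected igraph graph
#'
#' Node attributes: `type` (mirna/gene) and `log2_fc`; edge attributes:
#' `pcc_normal`, `pcc_tumor`, `delta`, `direction`.
#'
#' @param mgdrn an [MGDRN-class].
#' @return an [igraph::igraph] object.
#' @export
mgdrnGraph <- function(mgdrn) {
  stopifnot(is(mgdrn, "MGDRN"))
  igraph::graph_from_data_frame(mgdrn@edges, directed = FALSE,
                                vertices = mgdrn@nodes)
}

#' Write MGDRN edge table and GraphML
#'
#' @param mgdrn an [MGDRN-class].
#' @param tsvPath path for the edge TSV (mirna, gene, pcc_normal, pcc_tumor,
#'   delta, direction); `NULL` to skip.
#' @param graphmlPath path for a GraphML export with node/edge attributes;
#'   `NULL` to skip.
#' @export
writeMGDRN <- function(mgdrn, tsvPath = NULL, graphmlPath = NULL) {
  if (!is.null(tsvPath))
    write.table(mgdrn@edges, tsvPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(graphmlPath)) {
    g <- mgdrnGraph(mgdrn)
    igraph::V(g)$log2_fc[is.na(igraph::V(g)$log2_fc)] <- NaN
    igraph::write_graph(g, graphmlPath, format = "graphml")
  }
  invisible(mgdrn)
}
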