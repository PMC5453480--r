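#' Load pathway gene sets from a GMT file
#'
#' Standard GMT: one pathway per line, `id<TAB>description<TAB>gene...`.
#' Gene ids are normalized (lower-case, stripped) to match the catalog
#' namespace. Lines with fewer than three fields, empty gene sets and
#' duplicated pathway ids are fatal.
#'
#' @param path path to the GMT file.
#' @return a [PathwayCollection-class].
#' @export
loadGMT <- function(path) {
  if (!file.exists(path)) stop("cannot read GMT: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(trimws(f))]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, " in ", path,
           ": need id, description and >= 1 gene")
    id <- normalizeId(f[1L])
    if (id %in% names(sets))
      stop("duplicate pathway id '", id, "' at GMT line ", i)
    sets[[id]] <- unique(normalizeId(f[-(1:2)]))
    desc[[id]] <- f[2L]
  }
  new("PathwayCollection", sets = sets, descriptions = desc)
}

#' Hypergeometric over-representation of a target set in a pathway
#'
#' Exact upper-tail hypergeometric probability of drawing at least the
#' observed overlap: population = universe, successes = pathway genes in the
#' universe, draws = target genes in the universe. Targets and pathway are
#' intersected with the universe first. The EASE variant scores the overlap
#' minus one (more conservative for small overlaps).
#'
#' @param targets character vector of gene ids (a miRNA's dysregulated
#'   targets).
#' @param pathway character vector of pathway gene ids.
#' @param universe non-empty character vector: the background gene set.
#' @param ease use the EASE (overlap - 1) variant.
#' @return list with `overlap_count`, `target_count`,
#'   `pathway_count_in_universe`, `universe_size`, `p_value`.
#' @examples
#' u <- paste0("g", 1:20)
#' enrichTargets(u[1:5], u[1:5], u)$p_value  # 1 / choose(20, 5)
#' @export
enrichTargets <- function(targets, pathway, universe, ease = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  targets <- intersect(unique(targets), universe)
  pathway <- intersect(unique(pathway), universe)
  k <- length(intersect(targets, pathway))
  n <- length(targets); K <- length(pathway); N <- length(universe)
  q <- if (ease) k - 1L else k
  p <- if (q <= 0L) 1 else
    stats::phyper(q - 1L, K, N - K, n, lower.tail = FALSE)
  list(overlap_count = k, target_count = n,
       pathway_count_in_universe = K, universe_size = N,
       p_value = min(p, 1))
}

#' Per-miRNA pathway enrichment over MGDRN targets
#'
#' For every miRNA in the network, tests its dysregulated target gene set
#' against every pathway with [enrichTargets()].
#'
#' @param mgdrn an [MGDRN-class].
#' @param pathways a [PathwayCollection-class].
#' @param universe background gene set; conventionally the catalog genes
#'   that are also measured in the expression data.
#' @param adjust `"none"` (raw p, as is conventional for per-list pathway
#'   screens at p < 0.05) or `"BH"` for Benjamini-Hochberg within each
#'   miRNA's row.
#' @param ease passed to [enrichTargets()].
#' @return data.frame (`mirna`, `pathway`, `overlap`, `targets`,
#'   `pathway_size`, `p_value`).
#' @export
enrichmentTable <- function(mgdrn, pathways, universe,
                            adjust = c("none", "BH"), ease = FALSE) {
  adjust <- match.arg(adjust)
  stopifnot(is(mgdrn, "MGDRN"), is(pathways, "PathwayCollection"))
  edges <- mgdrn@edges
  targetsOf <- split(edges$gene, edges$mirna)
  sets <- pathwaySets(pathways)
  rows <- lapply(names(targetsOf), function(m) {
    recs <- lapply(names(sets), function(q)
      enrichTargets(targetsOf[[m]], sets[[q]], universe, ease))
    p <- vapply(recs, `[[`, numeric(1L), "p_value")
    if (adjust == "BH") p <- stats::p.adjust(p, "BH")
    data.frame(mirna = m, pathway = names(sets),
               overlap = vapply(recs, `[[`, integer(1L), "overlap_count"),
               targets = vapply(recs, `[[`, integer(1L), "target_count"),
               pathway_size = vapply(recs, `[[`, integer(1L),
                                     "pathway_count_in_universe"),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Significance matrix of -log10(p) enrichment scores
#'
#' Cell (miRNA, pathway) holds `-log10(p)` when the enrichment p-value is
#' strictly below `alpha`, and 0 otherwise. Rows and columns with no
#' significant cell are dropped before clustering.
#'
#' @inheritParams enrichmentTable
#' @param alpha per-cell significance level (default 0.05).
#' @return a [SignificanceMatrix-class].
#' @export
significanceMatrix <- function(mgdrn, pathways, universe, alpha = 0.05,
                               adjust = c("none", "BH"), ease = FALSE) {
  tab <- enrichmentTable(mgdrn, pathways, universe, adjust, ease)
  mirnas <- sort(unique(tab$mirna))
  paths <- names(pathwaySets(pathways))
  m <- matrix(0, length(mirnas), length(paths),
              dimnames = list(mirnas, paths))
  sig <- tab$p_value < alpha
  m[cbind(match(tab$mirna[sig], mirnas),
          match(tab$pathway[sig], paths))] <-
    -log10(pmax(tab$p_value[sig], 1e-300))
  m <- m[rowSums(m > 0) > 0, colSums(m > 0) > 0, drop = FALSE]
  new("SignificanceMatrix", scores = m, alpha = alpha)
}

# All member sets of the subtrees of an hclust dendrogram (every cluster
# obtainable from any cut), restricted to sets of at least minSize leaves.
subtreeSets <- function(hc, labels, minSize) {
  n <- length(labels)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) labels[-j] else members[[j]]
    members[[i]] <- c(pick(hc$merge[i, 1L]), pick(hc$merge[i, 2L]))
  }
  members[lengths(members) >= minSize]
}

#' Extract synergy modules by bi-directional hierarchical clustering
#'
#' Rows (miRNAs) and columns (pathways) of the significance matrix are
#' clustered independently (Euclidean distance, chosen linkage). Every
#' subtree of each dendrogram — i.e. every cluster obtainable from any cut —
#' that meets the size minima defines a candidate block together with a
#' subtree of the other dimension. A block is reported as a module when the
#' fraction of significant (nonzero) cells in it is at least `minDensity`.
#' Blocks are ranked by density, then size; a block overlapping an already
#' accepted module in both dimensions simultaneously is discarded, so
#' reported modules never overlap in both rows and columns at once.
#'
#' @param sm a [SignificanceMatrix-class].
#' @param linkage `"complete"` or `"average"`.
#' @param minDensity minimum fraction of nonzero cells (default 0.8).
#' @param minRows,minCols minimum block dimensions (default 2 x 2).
#' @return list of [SynergyModule-class], densest first.
#' @export
biclusterModules <- function(sm, linkage = c("complete", "average"),
                             minDensity = 0.8, minRows = 2L, minCols = 2L) {
  linkage <- match.arg(linkage)
  m <- scoreMatrix(sm)
  if (nrow(m) < minRows || ncol(m) < minCols) return(list())
  rowSets <- if (nrow(m) == minRows) list(rownames(m)) else
    subtreeSets(stats::hclust(stats::dist(m), method = linkage),
                rownames(m), minRows)
  colSets <- if (ncol(m) == minCols) list(colnames(m)) else
    subtreeSets(stats::hclust(stats::dist(t(m)), method = linkage),
                colnames(m), minCols)
  cand <- list()
  for (rs in rowSets) for (cs in colSets) {
    dens <- mean(m[rs, cs, drop = FALSE] > 0)
    if (dens >= minDensity)
      cand[[length(cand) + 1L]] <-
        list(rows = sort(rs), cols = sort(cs), density = dens)
  }
  if (!length(cand)) return(list())
  size <- vapply(cand, function(b) length(b$rows) * length(b$cols), 0)
  dens <- vapply(cand, `[[`, numeric(1L), "density")
  tag <- vapply(cand, function(b)
    paste(c(b$rows, "|", b$cols), collapse = ","), "")
  ord <- order(-dens, -size, tag)
  accepted <- list()
  for (i in ord) {
    b <- cand[[i]]
    clash <- any(vapply(accepted, function(a)
      length(intersect(a@mirnas, b$rows)) > 0 &&
        length(intersect(a@pathways, b$cols)) > 0, logical(1L)))
    if (!clash)
      accepted[[length(accepted) + 1L]] <-
        new("SynergyModule", mirnas = b$rows, pathways = b$cols,
            density = b$density)
  }
  accepted
}

#' Write enrichment results, the significance matrix and modules
#'
#' @param enrichment data.frame from [enrichmentTable()]; `NULL` to skip.
#' @param sm a [SignificanceMatrix-class]; `NULL` to skip.
#' @param modules list from [biclusterModules()]; `NULL` to skip.
#' @param enrichmentPath,matrixPath,modulesPath output paths (TSV, TSV,
#'   JSON).
#' @export
writeSynergyResults <- function(enrichment = NULL, sm = NULL, modules = NULL,
                                enrichmentPath = NULL, matrixPath = NULL,
                                modulesPath = NULL) {
  if (!is.null(enrichment) && !is.null(enrichmentPath))
    write.table(enrichment, enrichmentPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(sm) && !is.null(matrixPath))
    write.table(data.frame(mirna = rownames(scoreMatrix(sm)),
                           scoreMatrix(sm), check.names = FALSE),
                matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(modules) && !is.null(modulesPath))
    jsonlite::write_json(
      lapply(modules, function(mod)
        list(mirnas = moduleMirnas(mod), pathways = modulePathways(mod),
             density = moduleDensity(mod))),
      modulesPath, pretty = TRUE, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Clustered heatmap of the significance matrix
#'
#' Renders the bi-directionally clustered -log10(p) heatmap to a PNG.
#'
#' @param sm a [SignificanceMatrix-class] with >= 2 rows and columns.
#' @param path output PNG path.
#' @param linkage clustering linkage, as in [biclusterModules()].
#' @export
plotSynergyHeatmap <- function(sm, path, linkage = "complete") {
  m <- scoreMatrix(sm)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    warning("matrix too small to cluster; no heatmap written", call. = FALSE)
    return(invisible(NULL))
  }
  grDevices::png(path, width = 1200, height = 900, res = 120)
  on.exit(grDevices::dev.off())
  pheatmap::pheatmap(m, clustering_method = linkage,
                     clustering_distance_rows = "euclidean",
                     clustering_distance_cols = "euclidean",
                     main = "miRNA x pathway -log10(p)")
  invisible(path)
}
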