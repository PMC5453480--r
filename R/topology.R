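#' @importFrom igraph V degree betweenness distances vcount
NULL

asUndirectedGraph <- function(x) {
  if (is(x, "MGDRN")) mgdrnGraph(x)
  else if (igraph::is_igraph(x)) x
  else stop("expected an MGDRN or an igraph graph")
}

#' Node degree
#'
#' Number of edges incident to each node of the (simple, bipartite)
#' network, or to one named node.
#'
#' @param x an [MGDRN-class] or an igraph graph.
#' @param v optional single node id; if given, only that node's degree is
#'   returned and an unknown id is an error.
#' @return named integer vector of degrees (or a single integer).
#' @export
degreeCentrality <- function(x, v = NULL) {
  g <- asUndirectedGraph(x)
  d <- igraph::degree(g, loops = FALSE)
  if (!is.null(v)) {
    if (!v %in% names(d)) stop("unknown node: ", v)
    return(d[[v]])
  }
  d
}

#' Betweenness centrality
#'
#' Fraction of all-pairs shortest paths passing through each node, over
#' unordered node pairs with the endpoints excluded; unreachable pairs
#' contribute 0. The graph is treated as undirected and unweighted. With
#' `normalized = TRUE` the sum is divided by `(N - 1) (N - 2) / 2`, the
#' number of unordered pairs excluding the node, so values lie in [0, 1].
#' Graphs with fewer than 3 nodes score 0 everywhere.
#'
#' @param x an [MGDRN-class] or an igraph graph.
#' @param normalized divide by the pair count (default `TRUE`).
#' @return named numeric vector.
#' @export
betweennessCentrality <- function(x, normalized = TRUE) {
  g <- asUndirectedGraph(x)
  n <- vcount(g)
  if (n < 3L)
    return(stats::setNames(numeric(n), names(V(g))))
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  if (normalized) b <- b / ((n - 1) * (n - 2) / 2)
  b
}

#' Closeness centrality
#'
#' How close a node is to all others, from unweighted shortest-path
#' distances on the undirected graph. `mode = "raw"` returns the reciprocal
#' of the total distance to the nodes reachable from `v`,
#' `1 / sum(d(u, v))`. `mode = "normalized"` (default) returns the
#' Wasserman-Faust form `((r - 1) / sum(d)) * ((r - 1) / (N - 1))` with `r`
#' the size of `v`'s connected component, which corrects for disconnected
#' graphs and keeps values in [0, 1]. Isolated nodes score 0 in both modes.
#'
#' @param x an [MGDRN-class] or an igraph graph.
#' @param mode `"normalized"` or `"raw"`.
#' @return named numeric vector.
#' @export
closenessCentrality <- function(x, mode = c("normalized", "raw")) {
  mode <- match.arg(mode)
  g <- asUndirectedGraph(x)
  n <- vcount(g)
  d <- distances(g, weights = NA)
  out <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    r <- length(di) + 1L              # component size
    if (r == 1L || sum(di) == 0) return(0)
    if (mode == "raw") 1 / sum(di)
    else ((r - 1) / sum(di)) * ((r - 1) / (n - 1))
  }, numeric(1L))
  stats::setNames(out, rownames(d))
}

#' Centrality report for every node
#'
#' @param mgdrn an [MGDRN-class].
#' @param closenessMode passed to [closenessCentrality()].
#' @return data.frame (`node`, `type`, `degree`, `betweenness`,
#'   `closeness`), in node-table order.
#' @export
centralityTable <- function(mgdrn, closenessMode = "normalized") {
  g <- mgdrnGraph(mgdrn)
  data.frame(node = mgdrn@nodes$id, type = mgdrn@nodes$type,
             degree = unname(degreeCentrality(g)[mgdrn@nodes$id]),
             betweenness = unname(betweennessCentrality(g)[mgdrn@nodes$id]),
             closeness = unname(
               closenessCentrality(g, closenessMode)[mgdrn@nodes$id]),
             stringsAsFactors = FALSE)
}

#' Top-k nodes by a centrality score
#'
#' Nodes are sorted by score descending with ties broken lexicographically
#' by id; the first `k` are returned. With `ties = "all"`, every node tied
#' with the k-th value is included.
#'
#' @param values named numeric vector (node id -> score).
#' @param k number of nodes (>= 1).
#' @param nodeTypes optional named character vector (node id -> type) used
#'   with `restrictTo`.
#' @param restrictTo `"all"`, `"mirna"` or `"gene"`.
#' @param ties `"first"` (exactly k) or `"all"` (include k-th-value ties).
#' @return character vector of node ids.
#' @export
topK <- function(values, k, nodeTypes = NULL,
                 restrictTo = c("all", "mirna", "gene"),
                 ties = c("first", "all")) {
  restrictTo <- match.arg(restrictTo)
  ties <- match.arg(ties)
  if (k < 1L) stop("k must be >= 1")
  if (restrictTo != "all") {
    if (is.null(nodeTypes)) stop("restrictTo needs nodeTypes")
    values <- values[names(values) %in%
                       names(nodeTypes)[nodeTypes == restrictTo]]
  }
  ord <- order(-values, names(values))
  ids <- names(values)[ord]
  if (length(ids) < k) {
    warning("fewer than k = ", k, " nodes available; returning all",
            call. = FALSE)
    return(ids)
  }
  if (ties == "all" && length(ids) > k) {
    kth <- values[[ids[k]]]
    k <- max(which(values[ids] >= kth))
  }
  ids[seq_len(k)]
}

#' Key regulators: intersection of top-k lists
#'
#' Intersects the membership of the three top-k lists (by degree,
#' betweenness and closeness). With `normalizeArms = TRUE` a trailing
#' `-3p`/`-5p` arm suffix is stripped before comparing, so that the two
#' arms of one precursor count as the same regulator.
#'
#' @param byDegree,byBetweenness,byCloseness character vectors of node ids.
#' @param normalizeArms strip arm suffixes before intersecting.
#' @return character vector (sorted set) of normalized ids present in all
#'   three lists.
#' @export
keyRegulators <- function(byDegree, byBetweenness, byCloseness,
                          normalizeArms = TRUE) {
  norm <- function(x) if (normalizeArms) sub("-[35]p$", "", x) else x
  sort(Reduce(intersect, lapply(list(byDegree, byBetweenness, byCloseness),
                                function(l) unique(norm(l)))))
}

#' Write the centrality report and key-regulator summary
#'
#' @param mgdrn an [MGDRN-class].
#' @param tsvPath path for the centrality TSV; `NULL` to skip.
#' @param jsonPath path for a JSON report with the three top-k lists and
#'   their intersection; `NULL` to skip.
#' @param k list length for the top-k ranking (default 10).
#' @param restrictTo node type ranked in the top-k lists (default miRNAs).
#' @param closenessMode passed to [closenessCentrality()].
#' @return invisibly, the key-regulator list.
#' @export
writeTopologyReport <- function(mgdrn, tsvPath = NULL, jsonPath = NULL,
                                k = 10L, restrictTo = "mirna",
                                closenessMode = "normalized") {
  tab <- centralityTable(mgdrn, closenessMode)
  if (!is.null(tsvPath))
    write.table(tab, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  types <- stats::setNames(tab$type, tab$node)
  lists <- lapply(c(degree = "degree", betweenness = "betweenness",
                    closeness = "closeness"), function(col) {
    topK(stats::setNames(tab[[col]], tab$node), k, types, restrictTo)
  })
  report <- list(top_by_degree = lists$degree,
                 top_by_betweenness = lists$betweenness,
                 top_by_closeness = lists$closeness,
                 intersection = keyRegulators(lists$degree,
                                              lists$betweenness,
                                              lists$closeness))
  if (!is.null(jsonPath))
    jsonlite::write_json(report, jsonPath, pretty = TRUE)
  invisible(report)
}
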