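# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (plain loops, first-principles formulas) and
# share no code with the package internals.

# textbook product-moment correlation via explicit sums
oraclePearson <- function(x, y) {
  xb <- sum(x) / length(x); yb <- sum(y) / length(y)
  sum((x - xb) * (y - yb)) /
    sqrt(sum((x - xb)^2) * sum((y - yb)^2))
}

# upper-tail hypergeometric P(X >= k) by summing point masses with choose()
oracleHyper <- function(k, N, K, n) {
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  tot <- choose(N, n)
  sum(vapply(k:hi, function(i) choose(K, i) * choose(N - K, n - i), 0)) / tot
}

# BFS shortest-path distances and path counts from source s over an
# adjacency list (integer vectors, 1-based)
bfsCounts <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n); cnt <- numeric(n)
  dist[s] <- 0; cnt[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (u in frontier) for (v in adj[[u]]) {
      if (is.infinite(dist[v])) {
        dist[v] <- dist[u] + 1
        nxt <- c(nxt, v)
      }
      if (dist[v] == dist[u] + 1) cnt[v] <- cnt[v] + cnt[u]
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, cnt = cnt)
}

# all-pairs BFS path-counting centralities; edges: 2-column matrix of
# 1-based node indices, n: node count
oracleCentralities <- function(edges, n) {
  adj <- rep(list(integer()), n)
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  bfs <- lapply(seq_len(n), function(s) bfsCounts(adj, s))
  btw <- numeric(n)
  if (n >= 3) for (s in 1:(n - 1)) for (t in (s + 1):n) {
    ds <- bfs[[s]]$dist; dt <- bfs[[t]]$dist
    if (is.infinite(ds[t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(ds[v]) && is.finite(dt[v]) && ds[v] + dt[v] == ds[t])
        btw[v] <- btw[v] + bfs[[s]]$cnt[v] * bfs[[t]]$cnt[v] / bfs[[s]]$cnt[t]
    }
  }
  deg <- vapply(adj, length, 0L)
  closeRaw <- numeric(n); closeNorm <- numeric(n)
  for (v in seq_len(n)) {
    d <- bfs[[v]]$dist[-v]
    d <- d[is.finite(d)]
    r <- length(d) + 1
    if (r > 1 && sum(d) > 0) {
      closeRaw[v] <- 1 / sum(d)
      closeNorm[v] <- ((r - 1) / sum(d)) * ((r - 1) / (n - 1))
    }
  }
  btwNorm <- if (n >= 3) btw / ((n - 1) * (n - 2) / 2) else btw
  list(degree = deg, betweenness = btw, betweennessNorm = btwNorm,
       closenessRaw = closeRaw, closenessNorm = closeNorm)
}

# random simple bipartite graph as an igraph object plus its index edges
randomBipartite <- function(n1, n2, p) {
  ids <- c(paste0("m", seq_len(n1)), paste0("g", seq_len(n2)))
  pairs <- expand.grid(a = seq_len(n1), b = n1 + seq_len(n2))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- as.matrix(pairs[keep, , drop = FALSE])
  g <- igraph::make_empty_graph(n = n1 + n2, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(edges))
    g <- igraph::add_edges(g, t(cbind(edges[, 1L], edges[, 2L])))
  list(graph = g, edges = edges, n = n1 + n2, ids = ids)
}

# literal reimplementation of the catalog -> MGDRN stage: nested loops and
# first-principles formulas, applying each published filter in sequence
bruteForceDiffnet <- function(sourcePairs, geneMat, mirnaMat, condition,
                              minSources = 2, pseudocount = 0.01,
                              fcThreshold = 1, deltaThreshold = 0.2) {
  key <- paste(sourcePairs$mirna, sourcePairs$gene)
  counts <- tapply(sourcePairs$source, key, function(s) length(unique(s)))
  consensus <- names(counts)[counts >= minSources]
  normal <- names(condition)[condition == "normal"]
  tumor <- names(condition)[condition == "tumor"]
  out <- NULL
  for (k in consensus) {
    parts <- strsplit(k, " ")[[1L]]
    m <- parts[1L]; g <- parts[2L]
    if (!m %in% rownames(mirnaMat) || !g %in% rownames(geneMat)) next
    mt <- sum(geneMat[g, tumor]) / length(tumor)
    mn <- sum(geneMat[g, normal]) / length(normal)
    lfc <- log2((mt + pseudocount) / (mn + pseudocount))
    if (!(abs(lfc) > fcThreshold)) next
    pn <- oraclePearson(geneMat[g, normal], mirnaMat[m, normal])
    pt <- oraclePearson(geneMat[g, tumor], mirnaMat[m, tumor])
    if (is.na(pn) || is.na(pt)) next
    if (!(pn < 0 || pt < 0)) next
    delta <- pt - pn
    if (!(abs(delta) > deltaThreshold)) next
    out <- rbind(out, data.frame(
      mirna = m, gene = g, pcc_normal = pn, pcc_tumor = pt, delta = delta,
      direction = if (delta > 0) "up" else "down",
      stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(mirna = character(), gene = character(),
                      pcc_normal = numeric(), pcc_tumor = numeric(),
                      delta = numeric(), direction = character())
  out[order(out$mirna, out$gene), , drop = FALSE]
}
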