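graphOf <- function(edgeIds) {
  igraph::graph_from_data_frame(
    data.frame(from = edgeIds[, 1], to = edgeIds[, 2]), directed = FALSE)
}

test_that("degree counts incident edges", {
  star <- graphOf(cbind("c", paste0("l", 1:4)))
  expect_equal(degreeCentrality(star, "c"), 4L)
  expect_equal(degreeCentrality(star, "l1"), 1L)
  expect_error(degreeCentrality(star, "zz"), "unknown node")
  # degree sum = 2 * edge count on random graphs
  set.seed(2)
  for (i in 1:10) {
    rb <- randomBipartite(sample(3:10, 1), sample(3:10, 1), 0.3)
    expect_equal(sum(degreeCentrality(rb$graph)),
                 2L * igraph::ecount(rb$graph))
  }
})

test_that("betweenness matches the closed-form path and star cases", {
  path <- graphOf(cbind(c("a", "b"), c("b", "c")))
  b <- betweennessCentrality(path)
  expect_equal(b[["b"]], 1.0)
  expect_equal(b[["a"]], 0.0)
  star <- graphOf(cbind("c", paste0("l", 1:4)))
  expect_equal(betweennessCentrality(star)[["c"]], 1.0)
  expect_true(all(betweennessCentrality(star) >= 0))
  # < 3 nodes: all zeros
  expect_equal(unname(betweennessCentrality(graphOf(cbind("a", "b")))),
               c(0, 0))
})

test_that("closeness matches the reciprocal-distance and Wasserman-Faust
           forms", {
  path <- graphOf(cbind(c("a", "b"), c("b", "c")))
  craw <- closenessCentrality(path, "raw")
  expect_equal(craw[["b"]], 1 / 2)
  expect_equal(craw[["a"]], 1 / 3)
  # single component: normalized equals (N-1)/sum(d)
  cn <- closenessCentrality(path, "normalized")
  expect_equal(cn[["b"]], 2 / 2 * 1)
  expect_equal(cn[["a"]], 2 / 3)
  # two disjoint edges: each node scores (1/1) * (1/3)
  two <- graphOf(cbind(c("a", "c"), c("b", "d")))
  expect_equal(unname(closenessCentrality(two, "normalized")),
               rep(1 / 3, 4), tolerance = 1e-12)
})

test_that("centralities match brute-force BFS oracles on random bipartite
           graphs", {
  set.seed(9)
  for (i in 1:30) {
    rb <- randomBipartite(sample(3:15, 1), sample(3:15, 1), runif(1, .1, .5))
    o <- oracleCentralities(rb$edges, rb$n)
    expect_equal(unname(degreeCentrality(rb$graph)[rb$ids]), o$degree)
    expect_equal(unname(betweennessCentrality(rb$graph,
                                              normalized = FALSE)[rb$ids]),
                 o$betweenness, tolerance = 1e-9)
    expect_equal(unname(betweennessCentrality(rb$graph)[rb$ids]),
                 o$betweennessNorm, tolerance = 1e-9)
    expect_equal(unname(closenessCentrality(rb$graph, "raw")[rb$ids]),
                 o$closenessRaw, tolerance = 1e-9)
    got <- unname(closenessCentrality(rb$graph, "normalized")[rb$ids])
    expect_equal(got, o$closenessNorm, tolerance = 1e-9)
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("top-k ranks descending with lexicographic tie-break", {
  v <- c(a = 3, b = 2, c = 1)
  expect_equal(topK(v, 2), c("a", "b"))
  expect_equal(topK(c(a = 2, b = 2), 1), "a")
  expect_warning(all3 <- topK(v, 5), "fewer than")
  expect_equal(all3, c("a", "b", "c"))
  # ties = "all" returns every node tied at the k-th value
  expect_equal(topK(c(a = 2, b = 2, c = 1), 1, ties = "all"), c("a", "b"))
  # restriction by node type
  types <- c(a = "mirna", b = "gene", c = "mirna")
  expect_equal(topK(v, 2, types, restrictTo = "mirna"), c("a", "c"))
})

test_that("key regulators intersect the three lists with arm
           normalization", {
  l <- c("hsa-mir-1-3p", "hsa-mir-2")
  expect_setequal(keyRegulators(l, l, l), c("hsa-mir-1", "hsa-mir-2"))
  expect_equal(keyRegulators("a", "b", "c"), character())
  # order-independence and idempotence under arm normalization
  expect_equal(keyRegulators(rev(l), l, sample(l)),
               keyRegulators(l, l, l))
  byDegree <- c("hsa-mir-30e", "hsa-mir-142", "hsa-mir-203",
                "hsa-mir-152-3p", "hsa-mir-148a", "hsa-mir-130b",
                "hsa-mir-98", "hsa-mir-15b", "hsa-mir-30a", "hsa-mir-34a")
  byCloseness <- c("hsa-mir-152-3p", "hsa-mir-15b", "hsa-mir-130b",
                   "hsa-mir-301b", "hsa-mir-148b", "hsa-mir-148a",
                   "hsa-mir-181b", "hsa-mir-29b", "hsa-mir-30e",
                   "hsa-mir-142")
  byBetweenness <- c("hsa-mir-15b", "hsa-mir-130b", "hsa-mir-152",
                     "hsa-mir-142", "hsa-mir-148b", "hsa-mir-30e",
                     "hsa-mir-148a", "hsa-mir-98", "hsa-mir-511",
                     "hsa-mir-328")
  expect_setequal(keyRegulators(byDegree, byBetweenness, byCloseness),
                  c("hsa-mir-152", "hsa-mir-148a", "hsa-mir-130b",
                    "hsa-mir-15b", "hsa-mir-30e", "hsa-mir-142"))
})

test_that("centrality table and topology report cover every MGDRN node", {
  mg <- runDiffnetStages(randomSmallInstance(6))
  tab <- centralityTable(mg)
  expect_equal(tab$node, networkNodes(mg)$id)
  expect_true(all(tab$degree >= 1))        # no isolated nodes
  tsv <- tempfile(); json <- tempfile(fileext = ".json")
  k <- 3L
  rep <- suppressWarnings(writeTopologyReport(mg, tsv, json, k = k))
  expect_true(file.exists(tsv) && file.exists(json))
  back <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_length(back$top_by_degree, min(k, sum(tab$type == "mirna")))
  expect_setequal(back$intersection, rep$intersection)
})
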