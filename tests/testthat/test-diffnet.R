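test_that("pearson correlation matches hand-computed cases", {
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(1, 2, 3)), 1)
  # cov-sum 2; variance sums 2 and 14/3
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(2, 1, 4)),
               2 / sqrt(2 * 14 / 3), tolerance = 1e-12)
  expect_true(is.na(pearsonCorrelation(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearsonCorrelation(1:3, 1:4), "equal length")
  expect_error(pearsonCorrelation(1:2, 1:2), "at least 3")
})

test_that("pearson correlation equals the textbook formula on random pairs", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pearsonCorrelation(x, y), oraclePearson(x, y),
                 tolerance = 1e-12)
  }
})

smallNet <- function() {
  # two miRNAs, three genes; planted anticorrelation for (m1, g1) in both
  # conditions, positive correlation for (m1, g2), g3 not DE
  set.seed(5)
  n <- 30
  cond <- stats::setNames(rep(c("normal", "tumor"), each = n),
                          paste0("s", seq_len(2 * n)))
  m1 <- runif(2 * n, 10, 100); m2 <- runif(2 * n, 10, 100)
  g1 <- 300 - m1 + rnorm(2 * n, 0, 1)   # y = -x + small noise
  g2 <- m1 + rnorm(2 * n, 0, 1)
  g3 <- 300 - m2 + rnorm(2 * n, 0, 1)
  g1[cond == "tumor"] <- g1[cond == "tumor"] * 8  # make g1, g2 DE
  g2[cond == "tumor"] <- g2[cond == "tumor"] * 8
  geneMat <- rbind(g1 = g1, g2 = g2, g3 = g3)
  colnames(geneMat) <- names(cond)
  mirnaMat <- rbind(m1 = m1, m2 = m2)
  colnames(mirnaMat) <- names(cond)
  tabs <- list(mgdrn:::PredictionTable("s1", c("m1", "m1", "m2"),
                                       c("g1", "g2", "g3")),
               mgdrn:::PredictionTable("s2", c("m1", "m1", "m2"),
                                       c("g1", "g2", "g3")))
  list(geneExpr = ConditionedExpression(geneMat, cond),
       mirnaExpr = ConditionedExpression(mirnaMat, cond),
       catalog = buildCatalog(tabs, 2))
}

test_that("condition networks keep planted negative edges and apply the
           sign and DE filters", {
  s <- smallNet()
  net <- buildConditionNetwork(s$geneExpr, s$mirnaExpr, s$catalog,
                               c("g1", "g2"), "tumor")
  e <- networkEdges(net)
  expect_equal(nrow(e), 1L)                      # g2 positive, g3 not DE
  expect_equal(e$gene, "g1")
  expect_lt(abs(e$pcc - (-1)), 0.05)             # planted anticorrelation
  raw <- net@rawCorrelations
  expect_true("g2" %in% raw$gene)                # raw table keeps pcc > 0
  expect_false("g3" %in% raw$gene)               # DE filter is upstream
})

# construct a ConditionNetwork directly from a raw correlation table
netOf <- function(condition, mirna, gene, pcc) {
  raw <- data.frame(mirna = mirna, gene = gene, pcc = pcc)
  new("ConditionNetwork", condition = condition,
      edges = raw[raw$pcc < 0, , drop = FALSE], rawCorrelations = raw,
      nSkipped = 0L)
}

test_that("differential edges follow the delta threshold and direction
           rules", {
  mir <- c("m1", "m1", "m1", "m2")
  gen <- c("g1", "g2", "g3", "g4")
  nn <- netOf("normal", mir, gen, c(-0.60, -0.30, -0.05, 0.10))
  nt <- netOf("tumor", mir, gen, c(-0.10, -0.25, -0.60, -0.40))
  mg <- buildMGDRN(nn, nt, deltaThreshold = 0.2)
  e <- networkEdges(mg)
  expect_setequal(e$gene, c("g1", "g3", "g4"))   # |0.05| <= 0.2 excluded
  expect_equal(e$delta[e$gene == "g1"], 0.5)
  expect_equal(e$direction[e$gene == "g1"], "up")
  expect_equal(e$delta[e$gene == "g3"], -0.55)
  expect_equal(e$direction[e$gene == "g3"], "down")
  # g4: edge only in tumor; normal side taken raw (positive) and differenced
  expect_equal(e$delta[e$gene == "g4"], -0.5)
  # up + down counts partition the edge set
  expect_equal(sum(e$direction == "up") + sum(e$direction == "down"),
               nrow(e))
})

test_that("pairs with an undefined out-of-network correlation are skipped", {
  nn <- netOf("normal", "m1", "g1", -0.6)
  nt <- netOf("tumor", character(), character(), numeric())
  expect_message(mg <- buildMGDRN(nn, nt), "skipped")
  expect_equal(nrow(networkEdges(mg)), 0L)
})

test_that("swapping the condition networks flips directions and negates
           deltas", {
  for (seed in 1:5) {
    inst <- randomSmallInstance(seed)
    mg <- runDiffnetStages(inst)
    swapped <- inst
    swapped$condition <- stats::setNames(
      ifelse(inst$condition == "normal", "tumor", "normal"),
      names(inst$condition))
    mgSwap <- runDiffnetStages(swapped)
    a <- networkEdges(mg); b <- networkEdges(mgSwap)
    expect_equal(paste(a$mirna, a$gene), paste(b$mirna, b$gene))
    expect_equal(a$delta, -b$delta, tolerance = 1e-12)
    expect_equal(a$direction,
                 as.character(ifelse(b$direction == "up", "down", "up")))
  }
})

test_that("the full catalog->MGDRN stage matches a literal brute-force
           filter script", {
  for (seed in 1:8) {
    inst <- randomSmallInstance(seed)
    got <- networkEdges(runDiffnetStages(inst))
    want <- bruteForceDiffnet(inst$sourcePairs, inst$geneMat,
                              inst$mirnaMat, inst$condition)
    expect_equal(paste(got$mirna, got$gene), paste(want$mirna, want$gene))
    expect_equal(got$delta, want$delta, tolerance = 1e-10)
    expect_equal(got$direction, want$direction)
  }
})

test_that("MGDRN genes all pass the DE filter and pairs come from the
           catalog", {
  for (seed in 20:24) {
    inst <- randomSmallInstance(seed)
    mg <- runDiffnetStages(inst)
    geneExpr <- ConditionedExpression(inst$geneMat, inst$condition)
    deGenes <- selectDifferential(computeLog2FoldChange(geneExpr))
    e <- networkEdges(mg)
    expect_true(all(e$gene %in% deGenes))
    key <- paste(inst$sourcePairs$mirna, inst$sourcePairs$gene)
    expect_true(all(paste(e$mirna, e$gene) %in% key))
    expect_true(all(abs(e$delta) > 0.2))
    # node table is exactly the incident nodes, annotated with log2_fc
    expect_setequal(networkNodes(mg)$id, c(e$mirna, e$gene))
  }
})

test_that("MGDRN exports edge TSV and GraphML", {
  mg <- runDiffnetStages(randomSmallInstance(3))
  tsv <- tempfile(fileext = ".tsv"); gml <- tempfile(fileext = ".graphml")
  writeMGDRN(mg, tsv, gml)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(networkEdges(mg)))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(networkEdges(mg)))
  expect_setequal(igraph::vertex_attr(g, "type"),
                  networkNodes(mg)$type)
})
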