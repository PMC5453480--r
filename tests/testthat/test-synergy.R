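test_that("GMT files parse and reject malformed content", {
  ok <- writeTSV(c("PW1\tfirst pathway\tG1\tg2\tg3",
                   "pw2\tsecond\tg2\tg4"))
  pc <- loadGMT(ok)
  expect_length(pathwaySets(pc), 2L)
  expect_setequal(pathwaySets(pc)$pw1, c("g1", "g2", "g3"))
  expect_error(loadGMT(writeTSV("pw1\tdesc")), "line 1")
  expect_error(loadGMT(writeTSV(c("pw1\td\tg1", "pw1\td\tg2"))),
               "duplicate pathway")
  expect_error(loadGMT("/no/such.gmt"), "cannot read")
})

test_that("hypergeometric enrichment matches closed forms", {
  u <- paste0("g", 1:20)
  r <- enrichTargets(u[1:5], u[1:5], u)
  expect_equal(r$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(r$overlap_count, 5L)
  # pathway == universe: certain event
  expect_equal(enrichTargets(u[1:7], u, u)$p_value, 1)
  # zero overlap: P(X >= 0) = 1
  expect_equal(enrichTargets(u[1:5], u[6:10], u)$p_value, 1)
  expect_error(enrichTargets(u[1:2], u[1:2], character()), "empty universe")
  # EASE variant scores overlap - 1
  ease <- enrichTargets(u[1:5], u[1:5], u, ease = TRUE)
  expect_equal(ease$p_value, oracleHyper(4, 20, 5, 5), tolerance = 1e-12)
})

test_that("enrichment equals the combinatorial-sum oracle on random
           configurations", {
  set.seed(13)
  for (i in 1:60) {
    N <- sample(10:200, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    u <- paste0("g", seq_len(N))
    targets <- sample(u, n)
    pathway <- sample(u, K)
    r <- enrichTargets(targets, pathway, u)
    expect_equal(r$p_value, oracleHyper(r$overlap_count, N, K, n),
                 tolerance = 1e-10)
  }
})

test_that("p-values are monotone non-increasing in overlap at fixed
           margins", {
  u <- paste0("g", 1:50)
  pathway <- u[1:10]
  p <- vapply(0:8, function(k) {
    targets <- c(u[seq_len(k)], u[10 + seq_len(12 - k)])  # size 12, overlap k
    enrichTargets(targets, pathway, u)$p_value
  }, 0)
  expect_true(all(diff(p) <= 1e-15))
})

mgdrnOf <- function(mirna, gene) {
  e <- data.frame(mirna = mirna, gene = gene,
                  pcc_normal = -0.8, pcc_tumor = -0.1, delta = 0.7,
                  direction = "up", stringsAsFactors = FALSE)
  ids <- c(sort(unique(mirna)), sort(unique(gene)))
  new("MGDRN", edges = e,
      nodes = data.frame(id = ids,
                         type = rep(c("mirna", "gene"),
                                    c(length(unique(mirna)),
                                      length(unique(gene)))),
                         log2_fc = NA_real_),
      deltaThreshold = 0.2)
}

test_that("significance matrix reproduces per-cell enrichment and drops
           empty rows", {
  u <- paste0("g", 1:40)
  mg <- mgdrnOf(rep(c("m1", "m2"), each = 5),
                c(u[1:5], u[31:35]))
  pw <- new("PathwayCollection",
            sets = list(pwA = u[1:6], pwB = u[11:20]),
            descriptions = c(pwA = "", pwB = ""))
  sm <- significanceMatrix(mg, pw, u, alpha = 0.05)
  m <- scoreMatrix(sm)
  # m1's five targets all sit in pwA -> significant; m2 nowhere -> dropped
  expect_equal(rownames(m), "m1")
  expect_equal(colnames(m), "pwA")
  pA <- enrichTargets(u[1:5], u[1:6], u)$p_value
  expect_equal(m["m1", "pwA"], -log10(pA), tolerance = 1e-12)
})

blockMatrix <- function() {
  m <- matrix(0, 7, 16,
              dimnames = list(paste0("m", 1:7), paste0("p", sprintf("%02d", 1:16))))
  m[1:3, 1:12] <- 3   # dense 3 x 12 block
  m[4:7, 13:16] <- 2  # dense 4 x 4 block
  new("SignificanceMatrix", scores = m, alpha = 0.05)
}

test_that("biclustering recovers noise-free planted blocks exactly", {
  mods <- biclusterModules(blockMatrix())
  expect_length(mods, 2L)
  byRows <- mods[[order(-vapply(mods, function(x) length(moduleMirnas(x)),
                                0))[1]]]
  expect_setequal(moduleMirnas(byRows), paste0("m", 4:7))
  expect_setequal(modulePathways(byRows), paste0("p", sprintf("%02d", 13:16)))
  other <- setdiff(seq_along(mods),
                   order(-vapply(mods, function(x) length(moduleMirnas(x)),
                                 0))[1])
  expect_setequal(moduleMirnas(mods[[other]]), paste0("m", 1:3))
  expect_true(all(vapply(mods, moduleDensity, 0) >= 0.8))
})

test_that("degenerate matrices yield no modules", {
  empty <- new("SignificanceMatrix",
               scores = matrix(0, 1, 1, dimnames = list("m", "p")),
               alpha = 0.05)
  expect_equal(biclusterModules(empty), list())
  allZero <- new("SignificanceMatrix",
                 scores = matrix(0, 4, 4,
                                 dimnames = list(paste0("m", 1:4),
                                                 paste0("p", 1:4))),
                 alpha = 0.05)
  expect_equal(biclusterModules(allZero), list())
})

test_that("planted blocks survive speckle noise and row/column
           permutation", {
  set.seed(21)
  recovered <- 0L
  for (rep in 1:10) {
    m <- matrix(0, 12, 20,
                dimnames = list(paste0("m", 1:12), paste0("p", 1:20)))
    m[1:3, 1:12] <- runif(36, 1.5, 4)
    m[4:7, 13:16] <- runif(16, 1.5, 4)
    noise <- matrix(runif(length(m)) < 0.1 & m == 0, nrow(m))
    m[noise] <- runif(sum(noise), 1.4, 2)
    perm <- m[sample(nrow(m)), sample(ncol(m))]
    mods <- biclusterModules(new("SignificanceMatrix", scores = perm,
                                 alpha = 0.05), minDensity = 0.8)
    truth <- new("SyntheticTruth",
                 trueEdges = data.frame(mirna = character(),
                                        gene = character()),
                 dysregulatedEdges = data.frame(mirna = character(),
                                                gene = character()),
                 deGenes = data.frame(),
                 moduleTruth = list(
                   list(mirnas = paste0("m", 1:3),
                        pathways = paste0("p", 1:12)),
                   list(mirnas = paste0("m", 4:7),
                        pathways = paste0("p", 13:16))))
    sc <- scoreModuleRecovery(mods, truth)
    if (all(sc >= 0.8)) recovered <- recovered + 1L
    # reported modules never overlap in both dimensions simultaneously
    if (length(mods) >= 2)
      for (a in seq_along(mods)) for (b in seq_len(a - 1L))
        expect_false(
          length(intersect(moduleMirnas(mods[[a]]),
                           moduleMirnas(mods[[b]]))) > 0 &&
          length(intersect(modulePathways(mods[[a]]),
                           modulePathways(mods[[b]]))) > 0)
  }
  expect_gte(recovered, 8L)
})

test_that("alpha = 1 marks every cell with possible overlap", {
  u <- paste0("g", 1:30)
  mg <- mgdrnOf(rep("m1", 4), u[1:4])
  pw <- new("PathwayCollection", sets = list(pwA = u[1:10], pwB = u[21:30]),
            descriptions = c(pwA = "", pwB = ""))
  m <- scoreMatrix(significanceMatrix(mg, pw, u, alpha = 1))
  expect_true(m["m1", "pwA"] > 0)  # overlap present, p < 1
})
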