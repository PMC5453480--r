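# Small fixture builders shared across tests; everything is generated in
# code at test time.

writeTSV <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# a random desk-scale instance of the diffnet inputs: iid lognormal
# expression with random mean shifts, random multi-source prediction pairs
randomSmallInstance <- function(seed, nMirnas = 12, nGenes = 25,
                                nPerCond = 8, nSources = 5) {
  set.seed(seed)
  mirnas <- paste0("mir", seq_len(nMirnas))
  genes <- paste0("g", seq_len(nGenes))
  samples <- paste0("s", seq_len(2 * nPerCond))
  condition <- stats::setNames(
    rep(c("normal", "tumor"), each = nPerCond), samples)
  mirnaMat <- matrix(exp(rnorm(nMirnas * length(samples), log(50), 0.6)),
                     nMirnas, dimnames = list(mirnas, samples))
  shift <- sample(c(-2, 0, 2), nGenes, replace = TRUE)
  geneMat <- matrix(exp(rnorm(nGenes * length(samples), log(50), 0.6)),
                    nGenes, dimnames = list(genes, samples))
  geneMat[, condition == "tumor"] <-
    geneMat[, condition == "tumor"] * 2^shift
  nPairs <- sample(20:60, 1)
  sourcePairs <- data.frame(
    mirna = sample(mirnas, nPairs, replace = TRUE),
    gene = sample(genes, nPairs, replace = TRUE),
    source = sample(paste0("s", seq_len(nSources)), nPairs, replace = TRUE),
    stringsAsFactors = FALSE)
  sourcePairs <- unique(sourcePairs)
  list(sourcePairs = sourcePairs, geneMat = geneMat, mirnaMat = mirnaMat,
       condition = condition)
}

# run the package's catalog -> MGDRN path on a randomSmallInstance
runDiffnetStages <- function(inst, minSources = 2, deltaThreshold = 0.2) {
  tables <- lapply(split(inst$sourcePairs, inst$sourcePairs$source),
                   function(d) mgdrn:::PredictionTable(d$source[1L],
                                                      d$mirna, d$gene))
  catalog <- buildCatalog(unname(tables), minSources)
  geneExpr <- ConditionedExpression(inst$geneMat, inst$condition)
  mirnaExpr <- ConditionedExpression(inst$mirnaMat, inst$condition)
  deTab <- computeLog2FoldChange(geneExpr)
  deGenes <- selectDifferential(deTab)
  nn <- suppressWarnings(
    buildConditionNetwork(geneExpr, mirnaExpr, catalog, deGenes, "normal"))
  nt <- suppressWarnings(
    buildConditionNetwork(geneExpr, mirnaExpr, catalog, deGenes, "tumor"))
  suppressMessages(buildMGDRN(nn, nt, deTab, deltaThreshold))
}

# tiny generator settings for fast Monte-Carlo checks (full sample size,
# reduced population)
tinyConfig <- function(seed, ...) {
  syntheticConfig(nGenes = 40L, nMirnas = 8L, nTrueEdges = 20L,
                  nDysregulatedEdges = 10L, decoyPairCount = 20L,
                  pathwayCount = 6L, pathwaySize = 10L,
                  plantedModules = list(c(mirnas = 2L, pathways = 2L)),
                  moduleTargetsPerMirna = 4L, seed = seed, ...)
}
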