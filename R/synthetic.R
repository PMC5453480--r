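#' Configuration for the synthetic dataset generator
#'
#' Returns the default generator configuration, with any field overridden
#' by name. The defaults describe a desk-scale study: 200 genes and 50
#' miRNAs over 60 normal + 60 tumor samples; 150 true miRNA-target
#' couplings of which 100 are dysregulated (raw-scale correlation -0.7 in
#' normal, attenuated to -0.1 in tumor); coupled target genes shifted by
#' |log2 FC| = 2 in tumor; 7 prediction sources; 200 decoy pairs of which
#' 10% appear in more than one source; 30 pathways of 20 genes with two
#' planted synergy blocks of 3 miRNAs x 12 pathways and 4 miRNAs x 4
#' pathways.
#'
#' @param ... named overrides of any default field.
#' @return named list of generator settings.
#' @export
syntheticConfig <- function(...) {
  cfg <- list(
    nGenes = 200L, nMirnas = 50L,
    nNormalSamples = 60L, nTumorSamples = 60L,
    nTrueEdges = 150L, nDysregulatedEdges = 100L,
    pccNormalTarget = -0.7, pccTumorTargetDysregulated = -0.1,
    deLog2fcMagnitude = 2,
    nSources = 7L, decoyPairCount = 200L, decoyMultiFraction = 0.1,
    pathwayCount = 30L, pathwaySize = 20L,
    plantedModules = list(c(mirnas = 3L, pathways = 12L),
                          c(mirnas = 4L, pathways = 4L)),
    moduleTargetsPerMirna = 6L,
    noiseSd = 0.4,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

# correlation of (exp(X), exp(Y)) for bivariate normal (X, Y) with log-scale
# correlation rho and sds s1, s2 (closed form for the lognormal pair)
lognormalCorr <- function(rho, s1, s2) {
  (exp(rho * s1 * s2) - 1) /
    sqrt((expm1(s1^2)) * (expm1(s2^2)))
}

# find the log-scale correlation whose exponentiated (raw-scale) correlation
# equals targetRaw, by bisection; lognormalCorr is monotone in rho
calibrateLogCorr <- function(targetRaw, s) {
  stopifnot(targetRaw <= 0, targetRaw > lognormalCorr(-1, s, s))
  lo <- -1; hi <- 0
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (lognormalCorr(mid, s, s) < targetRaw) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

validateSyntheticConfig <- function(cfg) {
  with(cfg, {
    if (nNormalSamples < 3L || nTumorSamples < 3L)
      stop("need >= 3 samples per condition")
    if (nTrueEdges > nGenes)
      stop("more true edges than genes (each coupled gene has one regulator)")
    if (nDysregulatedEdges > nTrueEdges)
      stop("dysregulated edges must be a subset of true edges")
    if (nSources < 2L) stop("need >= 2 prediction sources")
    s <- noiseSd
    bound <- lognormalCorr(-1, s, s)
    for (x in c(pccNormalTarget, pccTumorTargetDysregulated))
      if (x >= 0 || x <= bound)
        stop("target correlation ", x, " outside the reachable range (",
             round(bound, 3), ", 0) at noiseSd = ", s)
    if (abs(pccNormalTarget - pccTumorTargetDysregulated) <= 0.2)
      warning("planted correlation difference does not exceed the default ",
              "delta threshold of 0.2; dysregulated edges may be ",
              "unrecoverable", call. = FALSE)
    nModMirnas <- sum(vapply(plantedModules, `[[`, 0L, 1L))
    if (nModMirnas > nMirnas)
      stop("planted modules need more miRNAs than exist")
    if (sum(vapply(plantedModules, `[[`, 0L, 2L)) > pathwayCount)
      stop("planted modules need more pathways than exist")
    if (nModMirnas * moduleTargetsPerMirna > nDysregulatedEdges)
      stop("planted modules need more dysregulated edges than configured")
  })
  invisible(cfg)
}

withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Generate a synthetic dataset with planted regulatory structure
#'
#' Emulates the inputs of the full pipeline. miRNA expression is drawn
#' log-normal; each planted "true edge" couples one target gene to one
#' miRNA on the log scale with a log-scale correlation calibrated (by
#' bisection against the closed-form lognormal correlation) so that the
#' raw-scale Pearson correlation matches the configured target —
#' `pccNormalTarget` in both conditions for stable edges, attenuated to
#' `pccTumorTargetDysregulated` in tumor for dysregulated edges. Every
#' coupled gene receives a tumor mean shift of `+-deLog2fcMagnitude` on the
#' log2 scale. Prediction tables use precursor miRNA ids (exercising the
#' mature-id conversion); every true edge appears in at least two sources,
#' decoy pairs in one source (or a few sources for a `decoyMultiFraction`
#' of them, exercising the correlation filters). Pathway gene sets are
#' built so that planted module miRNAs have their dysregulated targets
#' concentrated in their module pathways. Fully reproducible from
#' `config$seed`; the caller's RNG state is left untouched.
#'
#' @param config list from [syntheticConfig()].
#' @return list with elements `geneExpr`, `mirnaExpr`
#'   ([ConditionedExpression-class]), `predictionTables` (list of
#'   [PredictionTable-class] in the precursor namespace), `matureMap`
#'   (data.frame `pre_id`, `mature_id`), `pathways`
#'   ([PathwayCollection-class]), `truth` ([SyntheticTruth-class]) and
#'   `config`.
#' @export
simulateDataset <- function(config = syntheticConfig()) {
  validateSyntheticConfig(config)
  withLocalSeed(config$seed, generateDatasetImpl(config))
}

generateDatasetImpl <- function(cfg) {
  s <- cfg$noiseSd
  genes <- sprintf("gene%03d", seq_len(cfg$nGenes))
  pre <- sprintf("hsa-mir-%03d", seq_len(cfg$nMirnas))
  mature <- paste0(pre, "-3p")
  samples <- c(sprintf("n%03d", seq_len(cfg$nNormalSamples)),
               sprintf("t%03d", seq_len(cfg$nTumorSamples)))
  condition <- stats::setNames(
    rep(c("normal", "tumor"), c(cfg$nNormalSamples, cfg$nTumorSamples)),
    samples)
  nS <- length(samples)

  # -- plant edges: module miRNAs get their quota of dysregulated targets
  modMirnaIdx <- list(); used <- 0L
  for (pm in cfg$plantedModules) {
    modMirnaIdx[[length(modMirnaIdx) + 1L]] <- used + seq_len(pm[[1L]])
    used <- used + pm[[1L]]
  }
  geneSlots <- sample(genes)            # shuffled; one regulator per gene
  edgeMirna <- character(); edgeGene <- character()
  gi <- 0L
  for (idx in modMirnaIdx) for (m in idx) {
    edgeMirna <- c(edgeMirna, rep(mature[m], cfg$moduleTargetsPerMirna))
    edgeGene <- c(edgeGene, geneSlots[gi + seq_len(cfg$moduleTargetsPerMirna)])
    gi <- gi + cfg$moduleTargetsPerMirna
  }
  nRemainingDys <- cfg$nDysregulatedEdges - length(edgeMirna)
  nStable <- cfg$nTrueEdges - cfg$nDysregulatedEdges
  extraMirna <- sample(mature, nRemainingDys + nStable, replace = TRUE)
  extraGene <- geneSlots[gi + seq_len(nRemainingDys + nStable)]
  edgeMirna <- c(edgeMirna, extraMirna)
  edgeGene <- c(edgeGene, extraGene)
  isDys <- seq_along(edgeMirna) <= cfg$nDysregulatedEdges
  trueEdges <- data.frame(
    mirna = edgeMirna, gene = edgeGene,
    pcc_normal = cfg$pccNormalTarget,
    pcc_tumor = ifelse(isDys, cfg$pccTumorTargetDysregulated,
                       cfg$pccNormalTarget),
    stringsAsFactors = FALSE)

  # -- expression: log-normal miRNAs; coupled genes share the miRNA's
  #    standardized log score with the calibrated log-scale correlation
  rhoOf <- vapply(unique(c(cfg$pccNormalTarget,
                           cfg$pccTumorTargetDysregulated)),
                  calibrateLogCorr, numeric(1L), s = s)
  names(rhoOf) <- as.character(unique(c(cfg$pccNormalTarget,
                                        cfg$pccTumorTargetDysregulated)))
  muM <- stats::runif(cfg$nMirnas, log(5), log(500))
  zM <- matrix(stats::rnorm(cfg$nMirnas * nS), cfg$nMirnas, nS,
               dimnames = list(mature, samples))
  mirnaLog <- muM + s * zM
  muG <- stats::runif(cfg$nGenes, log(5), log(500))
  zG <- matrix(stats::rnorm(cfg$nGenes * nS), cfg$nGenes, nS,
               dimnames = list(genes, samples))
  geneLog <- muG + s * zG
  deSign <- sample(c(-1, 1), cfg$nGenes, replace = TRUE)
  deGenes <- data.frame(gene = trueEdges$gene,
                        log2_fc = deSign[match(trueEdges$gene, genes)] *
                          cfg$deLog2fcMagnitude,
                        stringsAsFactors = FALSE)
  tumorCols <- condition == "tumor"
  for (i in seq_len(nrow(trueEdges))) {
    g <- trueEdges$gene[i]; m <- trueEdges$mirna[i]
    for (cond in CONDITIONS) {
      cols <- condition == cond
      rho <- rhoOf[[as.character(
        if (cond == "normal") trueEdges$pcc_normal[i]
        else trueEdges$pcc_tumor[i])]]
      geneLog[g, cols] <- muG[match(g, genes)] +
        s * (rho * zM[m, cols] + sqrt(1 - rho^2) * zG[g, cols])
    }
  }
  shift <- deGenes$log2_fc[match(genes, deGenes$gene)] * log(2)
  shift[is.na(shift)] <- 0
  geneLog[, tumorCols] <- geneLog[, tumorCols] + shift
  geneExpr <- ConditionedExpression(exp(geneLog), condition)
  mirnaExpr <- ConditionedExpression(exp(mirnaLog), condition)

  # -- prediction tables (precursor namespace): true edges in >= 2 sources,
  #    single-source decoys, and a few multi-source decoys
  sources <- sprintf("src%d", seq_len(cfg$nSources))
  preOf <- stats::setNames(pre, mature)
  asgn <- list()
  addPair <- function(mir, gene, srcIdx) {
    for (k in srcIdx)
      asgn[[k]] <<- rbind(asgn[[k]],
                          data.frame(mirna = preOf[[mir]], gene = gene,
                                     stringsAsFactors = FALSE))
  }
  asgn <- rep(list(NULL), cfg$nSources)
  for (i in seq_len(nrow(trueEdges)))
    addPair(trueEdges$mirna[i], trueEdges$gene[i],
            sample(cfg$nSources, sample(2:cfg$nSources, 1L)))
  trueKey <- pairKey(trueEdges$mirna, trueEdges$gene)
  nDecoy <- cfg$decoyPairCount
  decoys <- unique(data.frame(
    mirna = sample(mature, 3L * nDecoy, replace = TRUE),
    gene = sample(genes, 3L * nDecoy, replace = TRUE),
    stringsAsFactors = FALSE))
  decoys <- decoys[!pairKey(decoys$mirna, decoys$gene) %in% trueKey, ,
                   drop = FALSE]
  if (nrow(decoys) < nDecoy)
    stop("infeasible config: not enough decoy pairs available")
  decoys <- decoys[seq_len(nDecoy), , drop = FALSE]
  nMulti <- round(cfg$decoyMultiFraction * nDecoy)
  for (i in seq_len(nDecoy)) {
    srcIdx <- if (i <= nMulti)
      sample(cfg$nSources, sample(2:min(3L, cfg$nSources), 1L))
    else sample(cfg$nSources, 1L)
    addPair(decoys$mirna[i], decoys$gene[i], srcIdx)
  }
  predictionTables <- lapply(seq_len(cfg$nSources), function(k) {
    p <- asgn[[k]]
    if (is.null(p)) PredictionTable(sources[k], character(), character())
    else PredictionTable(sources[k], p$mirna, p$gene)
  })
  matureMap <- data.frame(pre_id = pre, mature_id = mature,
                          stringsAsFactors = FALSE)

  # -- pathways with planted miRNA x pathway synergy blocks
  pwIds <- sprintf("pw%02d", seq_len(cfg$pathwayCount))
  sets <- vector("list", cfg$pathwayCount)
  names(sets) <- pwIds
  dysTargetsOf <- split(trueEdges$gene[isDys], trueEdges$mirna[isDys])
  moduleTruth <- list()
  pwUsed <- 0L
  for (j in seq_along(cfg$plantedModules)) {
    pm <- cfg$plantedModules[[j]]
    mirs <- mature[modMirnaIdx[[j]]]
    pws <- pwIds[pwUsed + seq_len(pm[[2L]])]
    pwUsed <- pwUsed + pm[[2L]]
    nPick <- ceiling(0.85 * cfg$moduleTargetsPerMirna)
    for (pw in pws) {
      core <- unlist(lapply(mirs, function(m)
        sample(dysTargetsOf[[m]], nPick)), use.names = FALSE)
      core <- unique(core)
      pad <- setdiff(genes, core)
      extra <- max(0L, cfg$pathwaySize - length(core))
      sets[[pw]] <- c(core, sample(pad, min(extra, length(pad))))
    }
    moduleTruth[[j]] <- list(mirnas = mirs, pathways = pws)
  }
  for (pw in pwIds[vapply(sets, is.null, logical(1L))])
    sets[[pw]] <- sample(genes, cfg$pathwaySize)
  pathways <- new("PathwayCollection", sets = sets,
                  descriptions = stats::setNames(
                    paste("synthetic pathway", pwIds), pwIds))

  list(geneExpr = geneExpr, mirnaExpr = mirnaExpr,
       predictionTables = predictionTables, matureMap = matureMap,
       pathways = pathways,
       truth = new("SyntheticTruth", trueEdges = trueEdges,
                   dysregulatedEdges = trueEdges[isDys, , drop = FALSE],
                   deGenes = deGenes, moduleTruth = moduleTruth),
       config = cfg)
}

#' Write a synthetic dataset in the pipeline's input dialects
#'
#' Writes `gene_expression.tsv`, `mirna_expression.tsv`, `conditions.tsv`,
#' one `predictions_<source>.tsv` per source, `mature_map.tsv`,
#' `pathways.gmt` and `truth.json` under `dir`.
#'
#' @param dataset list from [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return named list of written paths (prediction tables as a vector).
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  writeExpr <- function(ce, path) {
    v <- exprValues(ce)
    write.table(data.frame(entity_id = rownames(v), v, check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeExpr(dataset$geneExpr, p("gene_expression.tsv"))
  writeExpr(dataset$mirnaExpr, p("mirna_expression.tsv"))
  cond <- sampleCondition(dataset$geneExpr)
  write.table(data.frame(names(cond), unname(cond)), p("conditions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  predPaths <- vapply(dataset$predictionTables, function(t) {
    path <- p(paste0("predictions_", t@sourceName, ".tsv"))
    write.table(t@pairs, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    path
  }, "")
  write.table(dataset$matureMap, p("mature_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  sets <- pathwaySets(dataset$pathways)
  writeLines(vapply(names(sets), function(id)
    paste(c(id, dataset$pathways@descriptions[[id]], sets[[id]]),
          collapse = "\t"), ""), p("pathways.gmt"))
  truth <- dataset$truth
  jsonlite::write_json(
    list(true_edges = truth@trueEdges,
         dysregulated_edges = truth@dysregulatedEdges,
         de_genes = truth@deGenes,
         module_truth = truth@moduleTruth),
    p("truth.json"), dataframe = "columns", pretty = TRUE, digits = NA)
  list(geneExpression = p("gene_expression.tsv"),
       mirnaExpression = p("mirna_expression.tsv"),
       conditions = p("conditions.tsv"),
       predictionTables = predPaths,
       sourceNames = vapply(dataset$predictionTables,
                            function(t) t@sourceName, ""),
       matureMap = p("mature_map.tsv"),
       pathways = p("pathways.gmt"),
       truth = p("truth.json"))
}

#' Precision and recall of recovered dysregulated edges
#'
#' @param predicted data.frame with `mirna` and `gene` columns (e.g. the
#'   edge table of an [MGDRN-class]) or an `MGDRN`.
#' @param truth a [SyntheticTruth-class].
#' @return named numeric vector `c(precision =, recall =)`; precision is 0
#'   when nothing was predicted.
#' @export
scoreEdgeRecovery <- function(predicted, truth) {
  if (is(predicted, "MGDRN")) predicted <- networkEdges(predicted)
  stopifnot(is(truth, "SyntheticTruth"))
  predKey <- unique(pairKey(predicted$mirna, predicted$gene))
  trueKey <- pairKey(truth@dysregulatedEdges$mirna,
                     truth@dysregulatedEdges$gene)
  hit <- sum(predKey %in% trueKey)
  c(precision = if (length(predKey)) hit / length(predKey) else 0,
    recall = if (length(trueKey)) hit / length(trueKey) else 0)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Recovery score of planted synergy modules
#'
#' For each planted module, the best (over found modules) of the smaller of
#' the miRNA-set and pathway-set Jaccard indices against the truth.
#'
#' @param found list of [SynergyModule-class] from [biclusterModules()].
#' @param truth a [SyntheticTruth-class].
#' @return numeric vector, one score in [0, 1] per planted module.
#' @export
scoreModuleRecovery <- function(found, truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  vapply(truth@moduleTruth, function(tm) {
    if (!length(found)) return(0)
    max(vapply(found, function(f)
      min(jaccard(moduleMirnas(f), tm$mirnas),
          jaccard(modulePathways(f), tm$pathways)), numeric(1L)))
  }, numeric(1L))
}
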