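#' Pipeline run configuration
#'
#' Assembles the full run configuration: input paths, the analysis
#' thresholds (all defaulting to the conventional values used throughout
#' the package: consensus in >= 2 sources, |log2 FC| > 1, correlation
#' difference > 0.2, top 10, p < 0.05) and the output directory.
#'
#' @param geneExpression,mirnaExpression,conditions paths to the expression
#'   TSVs and the sample-condition map.
#' @param predictionTables character vector of prediction-table paths.
#' @param sourceNames source names parallel to `predictionTables`.
#' @param matureMap path to the pre->mature mapping TSV, or `NULL`.
#' @param pathways path to a GMT file.
#' @param outputDir directory for all artifacts.
#' @param minSources,log2fcThreshold,pseudocount,deltaThreshold,topK,alpha
#'   analysis parameters; see the stage functions.
#' @param deltaMode,closenessMode,linkage,minDensity,minModuleRows,minModuleCols
#'   method options passed through to [buildMGDRN()],
#'   [closenessCentrality()] and [biclusterModules()].
#' @param filterMirnasByFC also require miRNAs to pass the fold-change
#'   filter (by default only genes are filtered).
#' @param adjust multiple-testing mode for [enrichmentTable()].
#' @param heatmap render the clustered heatmap PNG.
#' @return named list.
#' @export
pipelineConfig <- function(geneExpression, mirnaExpression, conditions,
                           predictionTables, sourceNames, pathways,
                           outputDir, matureMap = NULL,
                           minSources = 2L, log2fcThreshold = 1,
                           pseudocount = 0.01, deltaThreshold = 0.2,
                           deltaMode = "signed", topK = 10L, alpha = 0.05,
                           closenessMode = "normalized",
                           linkage = "complete", minDensity = 0.8,
                           minModuleRows = 2L, minModuleCols = 2L,
                           filterMirnasByFC = FALSE, adjust = "none",
                           heatmap = TRUE) {
  cfg <- as.list(environment())
  stopifnot(cfg$log2fcThreshold > 0, cfg$deltaThreshold > 0,
            cfg$pseudocount > 0, cfg$alpha > 0, cfg$topK >= 1)
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds any subset of [pipelineConfig()]'s arguments by
#' name; `...` overrides take precedence over the file.
#'
#' @param path YAML file path.
#' @param ... named overrides.
#' @return named list as from [pipelineConfig()].
#' @export
loadPipelineConfig <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  raw <- lapply(raw, function(x)
    if (is.list(x) && length(x) && all(vapply(x, is.character, TRUE)))
      unlist(x) else x)
  over <- list(...)
  raw[names(over)] <- over
  do.call(pipelineConfig, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full differential-network pipeline
#'
#' Executes catalog -> differential expression -> condition networks ->
#' differential network -> topology -> pathway synergy, writing every
#' artifact under `config$outputDir`: `catalog.tsv`, `de_genes.tsv` (and
#' `de_mirnas.tsv`), `network_normal.tsv`/`network_tumor.tsv`,
#' `mgdrn_edges.tsv` + `mgdrn.graphml`, `centrality.tsv`,
#' `key_regulators.json`, `enrichment.tsv`, `significance_matrix.tsv`,
#' `modules.json`, `heatmap.png` and a parameter/count `run_log.txt`.
#' All tabular outputs are byte-reproducible for a fixed configuration.
#'
#' @param config list from [pipelineConfig()] or [loadPipelineConfig()].
#' @return invisibly, a list with the fitted objects (`catalog`, `deGenes`,
#'   `mgdrn`, `modules`, ...) and a `manifest` of written files.
#' @export
runPipeline <- function(config) {
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outputDir, f)
  manifest <- list()
  log <- c("mgdrn pipeline run",
           paste0("  ", names(config)[!vapply(config, is.null, TRUE)], " = ",
                  vapply(config[!vapply(config, is.null, TRUE)],
                         function(x) paste(format(x), collapse = ","), "")))

  catalog <- stage("catalog", {
    tables <- loadPredictionTables(config$predictionTables,
                                   config$sourceNames)
    if (!is.null(config$matureMap)) {
      map <- loadMatureMap(config$matureMap)
      tables <- lapply(tables, mapToMature, map = map)
    }
    buildCatalog(tables, config$minSources)
  })
  writeCatalog(catalog, out("catalog.tsv"))
  manifest$catalog <- out("catalog.tsv")
  log <- c(log, paste0("catalog: ", nrow(catalogRecords(catalog)),
                       " consensus pairs (minSources = ",
                       config$minSources, ")"))

  de <- stage("expression", {
    geneExpr <- loadExpression(config$geneExpression, config$conditions)
    mirnaExpr <- loadExpression(config$mirnaExpression, config$conditions)
    deGeneTab <- computeLog2FoldChange(geneExpr, config$pseudocount,
                                       config$log2fcThreshold)
    deMirnaTab <- computeLog2FoldChange(mirnaExpr, config$pseudocount,
                                        config$log2fcThreshold)
    list(geneExpr = geneExpr, mirnaExpr = mirnaExpr,
         deGeneTab = deGeneTab, deMirnaTab = deMirnaTab,
         deGenes = selectDifferential(deGeneTab, config$log2fcThreshold))
  })
  write.table(de$deGeneTab, out("de_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(de$deMirnaTab, out("de_mirnas.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$deGenes <- out("de_genes.tsv")
  manifest$deMirnas <- out("de_mirnas.tsv")
  log <- c(log, paste0("expression: ", length(de$deGenes), " of ",
                       nrow(de$deGeneTab), " genes pass |log2FC| > ",
                       config$log2fcThreshold))

  catalogUsed <- catalog
  if (isTRUE(config$filterMirnasByFC)) {
    deMirnas <- selectDifferential(de$deMirnaTab, config$log2fcThreshold)
    rec <- catalogRecords(catalog)
    catalogUsed <- new("InteractionCatalog",
                       records = rec[rec$mirna %in% deMirnas, ,
                                     drop = FALSE],
                       minSources = catalog@minSources)
    log <- c(log, paste0("expression: miRNA FC filter kept ",
                         nrow(catalogRecords(catalogUsed)), " pairs"))
  }

  nets <- stage("diffnet", {
    nn <- buildConditionNetwork(de$geneExpr, de$mirnaExpr, catalogUsed,
                                de$deGenes, "normal")
    nt <- buildConditionNetwork(de$geneExpr, de$mirnaExpr, catalogUsed,
                                de$deGenes, "tumor")
    list(normal = nn, tumor = nt)
  })
  for (cond in CONDITIONS) {
    write.table(networkEdges(nets[[cond]]),
                out(paste0("network_", cond, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest[[paste0("network_", cond)]] <- out(paste0("network_", cond,
                                                       ".tsv"))
    log <- c(log, paste0("diffnet: ", nrow(networkEdges(nets[[cond]])),
                         " negative-PCC edges in ", cond, " (",
                         nets[[cond]]@nSkipped, " undefined skipped)"))
  }

  mgdrn <- stage("diffnet", {
    deTable <- rbind(de$deGeneTab, de$deMirnaTab)
    buildMGDRN(nets$normal, nets$tumor, deTable, config$deltaThreshold,
               config$deltaMode)
  })
  writeMGDRN(mgdrn, out("mgdrn_edges.tsv"), out("mgdrn.graphml"))
  manifest$mgdrnEdges <- out("mgdrn_edges.tsv")
  manifest$mgdrnGraphml <- out("mgdrn.graphml")
  e <- networkEdges(mgdrn)
  log <- c(log, paste0("mgdrn: ", nrow(e), " edges (",
                       sum(e$direction == "up"), " up, ",
                       sum(e$direction == "down"), " down) between ",
                       sum(networkNodes(mgdrn)$type == "mirna"),
                       " miRNAs and ",
                       sum(networkNodes(mgdrn)$type == "gene"), " genes"))

  keyReg <- stage("topology",
    writeTopologyReport(mgdrn, out("centrality.tsv"),
                        out("key_regulators.json"), config$topK,
                        "mirna", config$closenessMode))
  manifest$centrality <- out("centrality.tsv")
  manifest$keyRegulators <- out("key_regulators.json")
  log <- c(log, paste0("topology: top-", config$topK,
                       " intersection has ", length(keyReg$intersection),
                       " miRNA(s): ",
                       paste(keyReg$intersection, collapse = ", ")))

  synergy <- stage("synergy", {
    pw <- loadGMT(config$pathways)
    universe <- intersect(unique(catalogRecords(catalogUsed)$gene),
                          rownames(de$geneExpr))
    enr <- enrichmentTable(mgdrn, pw, universe, config$adjust)
    sm <- significanceMatrix(mgdrn, pw, universe, config$alpha,
                             config$adjust)
    mods <- biclusterModules(sm, config$linkage, config$minDensity,
                             config$minModuleRows, config$minModuleCols)
    list(pathways = pw, enrichment = enr, sm = sm, modules = mods)
  })
  writeSynergyResults(synergy$enrichment, synergy$sm, synergy$modules,
                      out("enrichment.tsv"), out("significance_matrix.tsv"),
                      out("modules.json"))
  manifest$enrichment <- out("enrichment.tsv")
  manifest$significanceMatrix <- out("significance_matrix.tsv")
  manifest$modules <- out("modules.json")
  if (isTRUE(config$heatmap) && nrow(scoreMatrix(synergy$sm)) >= 2L &&
      ncol(scoreMatrix(synergy$sm)) >= 2L) {
    plotSynergyHeatmap(synergy$sm, out("heatmap.png"), config$linkage)
    manifest$heatmap <- out("heatmap.png")
  }
  log <- c(log, paste0("synergy: ", sum(synergy$enrichment$p_value <
                                          config$alpha),
                       " significant miRNA-pathway cells; ",
                       length(synergy$modules), " module(s)"))

  writeLines(log, out("run_log.txt"))
  manifest$runLog <- out("run_log.txt")
  invisible(list(catalog = catalog, de = de, networks = nets,
                 mgdrn = mgdrn, keyRegulators = keyReg,
                 enrichment = synergy$enrichment, sm = synergy$sm,
                 modules = synergy$modules, manifest = manifest,
                 log = log))
}

#' Simulate a dataset and run the pipeline on it
#'
#' Convenience wrapper: generates a synthetic dataset, writes it under
#' `file.path(dir, "input")`, runs the full pipeline into
#' `file.path(dir, "output")` and scores the result against the planted
#' truth.
#'
#' @param config generator configuration from [syntheticConfig()].
#' @param dir working directory for inputs and outputs.
#' @param ... overrides passed to [pipelineConfig()].
#' @return list with the pipeline `result`, the `dataset`, and the
#'   `edgeScore` / `moduleScore` truth comparisons.
#' @export
runSyntheticPipeline <- function(config = syntheticConfig(),
                                 dir = tempfile("mgdrn_run"), ...) {
  dataset <- simulateDataset(config)
  paths <- writeDataset(dataset, file.path(dir, "input"))
  pcfg <- pipelineConfig(
    geneExpression = paths$geneExpression,
    mirnaExpression = paths$mirnaExpression,
    conditions = paths$conditions,
    predictionTables = paths$predictionTables,
    sourceNames = paths$sourceNames,
    matureMap = paths$matureMap,
    pathways = paths$pathways,
    outputDir = file.path(dir, "output"), ...)
  result <- runPipeline(pcfg)
  list(result = result, dataset = dataset,
       edgeScore = scoreEdgeRecovery(result$mgdrn, dataset$truth),
       moduleScore = scoreModuleRecovery(result$modules, dataset$truth))
}
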