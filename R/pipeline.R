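#' Pipeline run configuration
#'
#' Collects every stage's parameters with their defaults. One global seed
#' deterministically derives all stage seeds (simulate: `seed`; control
#' sampling: `seed + 20`; clustering: `seed + 10`; metacells:
#' `seed + 30`), so partial re-runs reproduce full-run outputs.
#'
#' @param seed global seed.
#' @param sim a [simConfig()]; defaults to a fast-test-scale configuration
#'   (1,500 cells x 1,200 genes) suitable for smoke runs.
#' @param nHvgs,nPcs,kNeighbors,resolution preprocessing parameters.
#' @param B control sets for scoring.
#' @param weights `"none"` (unweighted) or `"zscore"` (gene-based z-scores
#'   as weights).
#' @param pLow,pHigh subcluster split thresholds.
#' @param degAlpha,log2fcMin up-DEG thresholds.
#' @param metacellK,maxShared,targetN metacell parameters.
#' @param minModuleSize,mergeCut,topModules network parameters.
#' @param rThreshold score-correlation candidate threshold.
#' @param fdrAlpha module-gene FDR threshold.
#' @return list of class `runConfig`.
#' @export
runConfig <- function(seed = 1, sim = NULL, nHvgs = 800, nPcs = 20,
                      kNeighbors = 20, resolution = 1, B = 100,
                      weights = "none", pLow = 0.01, pHigh = 0.1,
                      degAlpha = 0.05, log2fcMin = 0, metacellK = 25,
                      maxShared = 10, targetN = 250, minModuleSize = 30,
                      mergeCut = 0.2, topModules = 3, rThreshold = 0.01,
                      fdrAlpha = 0.05) {
  if (is.null(sim)) sim <- fastTestSimConfig(seed)
  weights <- match.arg(weights, c("none", "zscore"))
  cfg <- list(seed = as.integer(seed), sim = sim, nHvgs = nHvgs,
              nPcs = nPcs, kNeighbors = kNeighbors,
              resolution = resolution, B = B, weights = weights,
              pLow = pLow, pHigh = pHigh, degAlpha = degAlpha,
              log2fcMin = log2fcMin, metacellK = metacellK,
              maxShared = maxShared, targetN = targetN,
              minModuleSize = minModuleSize, mergeCut = mergeCut,
              topModules = topModules, rThreshold = rThreshold,
              fdrAlpha = fdrAlpha)
  class(cfg) <- "runConfig"
  cfg
}

#' Fast-test-scale simulation configuration
#'
#' 1,500 cells x 1,200 genes with the study's 87-gene disease set, 130
#' locus genes (10 undetected), 10 co-regulated bystanders, five 40-gene
#' modules and 4 outside-locus GWAS hits — the scaled-down study layout
#' used by smoke tests and end-to-end checks.
#'
#' @param seed master seed.
#' @return A [simConfig()].
#' @export
fastTestSimConfig <- function(seed = 1) {
  simConfig(nGenes = 1200, nCells = 1500, diseaseSetSize = 87,
            nLocusGenes = 130, nUndetectedLocusGenes = 10,
            nCoregBystanders = 10, moduleSizes = rep(40L, 5),
            moduleTadCounts = c(12, 8, 0, 0, 0), nOutsideHits = 4,
            nTads = 20, nMarkersPerType = 60, seed = seed)
}

#' Read a run configuration from YAML
#'
#' Top-level keys must be [runConfig()] arguments (unknown keys are
#' rejected); the `sim` key, if present, must hold [simConfig()]
#' arguments.
#'
#' @param path YAML file.
#' @return list of class `runConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(y$sim)) {
    simKnown <- names(formals(simConfig))
    simUnknown <- setdiff(names(y$sim), simKnown)
    if (length(simUnknown))
      stop("unknown sim config key(s): ",
           paste(simUnknown, collapse = ", "))
    if (!is.null(y$sim$cellTypes)) y$sim$cellTypes <- unlist(y$sim$cellTypes)
    if (!is.null(y$sim$affected))
      y$sim$affected <- as.data.frame(y$sim$affected)
    y$sim <- do.call(simConfig, y$sim)
  }
  do.call(runConfig, y)
}

requireStageFile <- function(path, stage) {
  if (!file.exists(path))
    stop("missing input ", basename(path),
         "; run the '", stage, "' stage first")
  path
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates simulate -> preprocess -> score -> assoc -> hetero ->
#' split-deg -> network -> prioritize -> enrich. Each stage reads its
#' inputs from and writes its outputs to `outdir` as TSV, so stages can be
#' re-run individually; a missing input names the stage that produces it.
#' A `manifest.yaml` records the effective configuration and stage seeds.
#'
#' @param config a [runConfig()].
#' @param outdir output directory.
#' @param stages character vector of stages to run, or `"all"`.
#' @return `outdir`, invisibly.
#' @export
runPipeline <- function(config = runConfig(), outdir,
                        stages = "all") {
  allStages <- c("simulate", "preprocess", "score", "assoc", "hetero",
                 "split-deg", "network", "prioritize", "enrich")
  if (identical(stages, "all")) stages <- allStages
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  for (st in stages) {
    switch(st,
      "simulate" = stageSimulate(config, outdir),
      "preprocess" = stagePreprocess(config, outdir),
      "score" = stageScore(config, outdir),
      "assoc" = stageAssoc(config, outdir),
      "hetero" = stageHetero(config, outdir),
      "split-deg" = stageSplitDeg(config, outdir),
      "network" = stageNetwork(config, outdir),
      "prioritize" = stagePrioritize(config, outdir),
      "enrich" = stageEnrich(config, outdir),
      stop("unknown stage: ", st))
  }
  manifest <- list(seed = config$seed,
                   stage_seeds = list(simulate = config$seed,
                                      cluster = config$seed + 10L,
                                      controls = config$seed + 20L,
                                      metacells = config$seed + 30L),
                   parameters = config[setdiff(names(config), "sim")],
                   sim = unclass(config$sim))
  manifest$parameters$sim <- NULL
  manifest$sim$affected <- as.list(config$sim$affected)
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(outdir)
}

stageSimulate <- function(config, outdir) {
  message("[simulate] generating synthetic inputs")
  indir <- file.path(outdir, "inputs")
  sim <- simulateCounts(config$sim)
  writeCounts(sim$sce, indir)
  gwas <- simulateGwas(sim$truth, config$sim)
  writeGwas(gwas, file.path(indir, "gwas.tsv"))
  tads <- simulateTads(sim$truth, config$sim)
  writeTads(tads, file.path(indir, "tads.bed"),
            file.path(indir, "tad_genes.tsv"))
  gt <- sim$truth$genes
  w <- if (config$weights == "zscore")
    gwas$z[match(gt$gene[gt$disease], gwas$gene)] else NULL
  set <- WeightedGeneSet(gt$gene[gt$disease],
                         weights = if (is.null(w)) rep(1, sum(gt$disease))
                                   else pmax(w, 0),
                         name = "disease_set")
  writeGeneSet(set, file.path(indir, "gene_set.tsv"))
  terms <- simulateTermMap(sim$truth, config$sim)
  writeGmt(terms, file.path(indir, "terms.gmt"))
  writeTsv(sim$truth$cells, file.path(indir, "truth_cells.tsv"))
  writeTsv(gt, file.path(indir, "truth_genes.tsv"))
  invisible(outdir)
}

loadInputs <- function(config, outdir) {
  indir <- file.path(outdir, "inputs")
  requireStageFile(file.path(indir, "matrix.mtx"), "simulate")
  sce <- readCounts(file.path(indir, "matrix.mtx"),
                    file.path(indir, "genes.tsv"),
                    file.path(indir, "barcodes.tsv"),
                    file.path(indir, "metadata.tsv"))
  normalizeLog1p(sce)
}

stagePreprocess <- function(config, outdir) {
  message("[preprocess] normalize, HVGs, PCA, clustering")
  sce <- loadInputs(config, outdir)
  hvgs <- selectHVGs(sce, n = config$nHvgs)
  sce <- embedPCA(sce, hvgs, nPcs = config$nPcs)
  emb <- SingleCellExperiment::reducedDim(sce, "PCA")
  labels <- clusterCells(sce, kNeighbors = config$kNeighbors,
                         resolution = config$resolution,
                         seed = config$seed + 10L)
  writeTsv(data.frame(cell = rownames(emb), emb, check.names = FALSE),
           file.path(outdir, "embeddings.tsv"))
  writeTsv(data.frame(cell = names(labels), cluster = unname(labels)),
           file.path(outdir, "clusters.tsv"))
  writeLines(hvgs, file.path(outdir, "hvgs.txt"))
  invisible(outdir)
}

stageScore <- function(config, outdir) {
  message("[score] disease-relevance scoring, B = ", config$B)
  sce <- loadInputs(config, outdir)
  set <- readGeneSet(requireStageFile(
    file.path(outdir, "inputs", "gene_set.tsv"), "simulate"))
  det <- filterDetectedGenes(geneIds(set), sce)
  if (length(det$undetected)) {
    keep <- geneIds(set) %in% det$detected
    set <- WeightedGeneSet(geneIds(set)[keep],
                           unname(geneWeights(set))[keep], setName(set))
  }
  bins <- computeGeneBins(sce)
  ctrl <- sampleControlSets(bins, set, B = config$B,
                            seed = config$seed + 20L)
  scores <- scoreCells(sce, set, ctrl)
  writeTsv(scoreTable(scores), file.path(outdir, "scores.tsv"))
  ctrlDf <- data.frame(cell = scores@cells,
                       round(controlScores(scores), 6),
                       check.names = FALSE)
  colnames(ctrlDf)[-1] <- sprintf("ctrl%03d", seq_len(config$B))
  writeTsv(ctrlDf, file.path(outdir, "control_scores.tsv"))
  qc <- qcDepthCorrelation(scores, sce)
  message("[score] depth-correlation QC: r = ", format(qc$r, digits = 3))
  writeTsv(data.frame(metric = "depth_correlation", value = qc$r),
           file.path(outdir, "score_qc.tsv"))
  invisible(outdir)
}

loadScores <- function(config, outdir) {
  st <- read.table(requireStageFile(file.path(outdir, "scores.tsv"),
                                    "score"), header = TRUE, sep = "\t")
  ctrl <- as.matrix(read.table(
    requireStageFile(file.path(outdir, "control_scores.tsv"), "score"),
    header = TRUE, sep = "\t", row.names = 1, check.names = FALSE))
  new("CellScores", cells = as.character(st$cell), raw = st$raw,
      normalized = st$normalized, pval = st$pval, fdr = st$fdr,
      controls = ctrl)
}

loadClusters <- function(config, outdir) {
  cl <- read.table(requireStageFile(file.path(outdir, "clusters.tsv"),
                                    "preprocess"), header = TRUE,
                   sep = "\t")
  setNames(cl$cluster, cl$cell)
}

loadEmbedding <- function(config, outdir) {
  emb <- read.table(requireStageFile(file.path(outdir, "embeddings.tsv"),
                                     "preprocess"), header = TRUE,
                    sep = "\t", row.names = 1, check.names = FALSE)
  as.matrix(emb)
}

stageAssoc <- function(config, outdir) {
  message("[assoc] cell-group association")
  scores <- loadScores(config, outdir)
  labels <- loadClusters(config, outdir)
  assoc <- groupAssociation(scores, labels)
  writeTsv(assoc, file.path(outdir, "group_assoc.tsv"))
  invisible(outdir)
}

stageHetero <- function(config, outdir) {
  message("[hetero] within-group heterogeneity")
  scores <- loadScores(config, outdir)
  labels <- loadClusters(config, outdir)
  emb <- loadEmbedding(config, outdir)
  het <- groupHeterogeneity(scores, emb, labels)
  writeTsv(het, file.path(outdir, "group_hetero.tsv"))
  invisible(outdir)
}

targetCluster <- function(config, outdir) {
  assoc <- read.table(requireStageFile(file.path(outdir,
                                                 "group_assoc.tsv"),
                                       "assoc"), header = TRUE, sep = "\t")
  assoc <- assoc[assoc$reliable, , drop = FALSE]
  assoc$group[order(assoc$p, -assoc$mean_score)][1]
}

stageSplitDeg <- function(config, outdir) {
  message("[split-deg] subcluster split and differential expression")
  sce <- loadInputs(config, outdir)
  scores <- loadScores(config, outdir)
  labels <- loadClusters(config, outdir)
  target <- targetCluster(config, outdir)
  message("[split-deg] target cluster: ", target)
  cells <- names(labels)[labels == target]
  split <- splitByScore(scores, cells, pLow = config$pLow,
                        pHigh = config$pHigh)
  writeTsv(data.frame(cell = names(split), label = unname(split),
                      cluster = target),
           file.path(outdir, "subclusters.tsv"))
  deg <- wilcoxonMarkers(sce, names(split)[split == "associated"],
                         names(split)[split == "non-associated"])
  writeTsv(deg, file.path(outdir, "markers.tsv"))
  tads <- readTads(file.path(outdir, "inputs", "tads.bed"),
                   file.path(outdir, "inputs", "tad_genes.tsv"))
  set <- readGeneSet(file.path(outdir, "inputs", "gene_set.tsv"))
  ov <- overlapWithAnnotation(deg, tads, set, alpha = config$degAlpha,
                              log2fcMin = config$log2fcMin)
  writeTsv(data.frame(metric = c("n_up", "n_up_tad", "n_up_disease"),
                      value = c(ov$n_up, ov$n_up_tad, ov$n_up_disease)),
           file.path(outdir, "deg_overlap.tsv"))
  writeTsv(ov$candidates, file.path(outdir, "deg_candidates.tsv"))
  invisible(outdir)
}

stageNetwork <- function(config, outdir) {
  message("[network] metacells and co-expression modules")
  sce <- loadInputs(config, outdir)
  labels <- loadClusters(config, outdir)
  target <- targetCluster(config, outdir)
  hvgs <- readLines(requireStageFile(file.path(outdir, "hvgs.txt"),
                                     "preprocess"))
  emb <- loadEmbedding(config, outdir)
  SingleCellExperiment::reducedDim(sce, "PCA") <- emb[colnames(sce), ,
                                                      drop = FALSE]
  mc <- buildMetacells(sce, target, labels, k = config$metacellK,
                       maxShared = config$maxShared,
                       targetN = config$targetN,
                       seed = config$seed + 30L)
  sp <- selectSoftPower(metacellExpr(mc)[hvgs, , drop = FALSE])
  writeTsv(sp$scan, file.path(outdir, "softpower.tsv"))
  ms <- detectModules(metacellExpr(mc)[sp$genes, , drop = FALSE],
                      sp$power, minModuleSize = config$minModuleSize,
                      mergeCut = config$mergeCut)
  tads <- readTads(file.path(outdir, "inputs", "tads.bed"),
                   file.path(outdir, "inputs", "tad_genes.tsv"))
  rank <- rankModulesByTadFraction(ms, tads, topN = config$topModules)
  lab <- moduleLabels(ms)
  kme <- moduleKME(ms)
  ownKme <- ifelse(lab > 0, kme[cbind(seq_along(lab),
                                      match(lab, colnames(kme)))], NA)
  writeTsv(data.frame(gene = names(lab), module = unname(lab),
                      kme = round(unname(ownKme), 6)),
           file.path(outdir, "modules.tsv"))
  eg <- moduleEigengenes(ms)
  writeTsv(data.frame(metacell = rownames(eg), round(eg, 6),
                      check.names = FALSE),
           file.path(outdir, "eigengenes.tsv"))
  writeTsv(rank, file.path(outdir, "module_rank.tsv"))
  hubs <- hubGenes(ms)
  writeTsv(data.frame(module = rep(names(hubs), lengths(hubs)),
                      gene = unlist(hubs, use.names = FALSE)),
           file.path(outdir, "hub_genes.tsv"))
  invisible(outdir)
}

loadModules <- function(config, outdir) {
  read.table(requireStageFile(file.path(outdir, "modules.tsv"),
                              "network"), header = TRUE, sep = "\t")
}

stagePrioritize <- function(config, outdir) {
  message("[prioritize] gene-set tests and candidate assembly")
  sce <- loadInputs(config, outdir)
  gwas <- readGwas(requireStageFile(
    file.path(outdir, "inputs", "gwas.tsv"), "simulate"))
  tads <- readTads(file.path(outdir, "inputs", "tads.bed"),
                   file.path(outdir, "inputs", "tad_genes.tsv"))
  set <- readGeneSet(file.path(outdir, "inputs", "gene_set.tsv"))
  mods <- loadModules(config, outdir)
  rank <- read.table(requireStageFile(file.path(outdir,
                                                "module_rank.tsv"),
                                      "network"), header = TRUE,
                     sep = "\t")
  selected <- rank$module[rank$selected]
  selList <- setNames(lapply(selected, function(m)
    mods$gene[mods$module == m]), as.character(selected))
  background <- intersect(rownames(sce), gwas$gene)
  tests <- do.call(rbind, lapply(names(selList), function(m)
    cbind(module = m,
          competitiveGeneSetTest(gwas, selList[[m]], background,
                                 covariates = "log_length"))))
  writeTsv(tests, file.path(outdir, "gene_set_tests.tsv"))
  mf <- moduleGeneFdr(gwas, selList, tads, alpha = config$fdrAlpha)
  writeTsv(mf, file.path(outdir, "module_gene_fdr.tsv"))
  scores <- loadScores(config, outdir)
  geneCor <- correlateScoreWithGenes(sce, scores)
  writeTsv(data.frame(gene = geneCor$gene, r = round(geneCor$r, 6)),
           file.path(outdir, "score_gene_cor.tsv"))
  lists <- scoreCorrelationCandidates(geneCor, tads, set,
                                      rThreshold = config$rThreshold)
  degCand <- read.table(requireStageFile(
    file.path(outdir, "deg_candidates.tsv"), "split-deg"),
    header = TRUE, sep = "\t",
    colClasses = c("character", "numeric", "numeric", "character"))
  cand <- assembleCandidateTable(degCand, lists, mf, set, tads)
  writeTsv(cand, file.path(outdir, "candidates.tsv"))
  invisible(outdir)
}

stageEnrich <- function(config, outdir) {
  message("[enrich] over-representation of the top module")
  sce <- loadInputs(config, outdir)
  terms <- readGmt(requireStageFile(
    file.path(outdir, "inputs", "terms.gmt"), "simulate"))
  mods <- loadModules(config, outdir)
  rank <- read.table(requireStageFile(file.path(outdir,
                                                "module_rank.tsv"),
                                      "network"), header = TRUE,
                     sep = "\t")
  top <- rank$module[rank$selected][1]
  geneList <- mods$gene[mods$module == top]
  enr <- overrepresentationTest(geneList, terms, rownames(sce))
  writeTsv(enr, file.path(outdir, "enrichment.tsv"))
  invisible(outdir)
}
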