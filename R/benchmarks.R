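#' Null calibration of per-cell scoring and group association
#'
#' Repeated null simulations (fold-effect 1.0): pooled per-cell empirical
#' p-values are compared with the uniform distribution
#' (Kolmogorov-Smirnov), and the group-association test's type-I error is
#' measured over random cell groups.
#'
#' @param nSeeds replicate simulations (default 20).
#' @param nCells,nGenes simulation scale (default 2000 x 1000).
#' @param B control sets per replicate (default 200).
#' @param nGroups random null groups per replicate (default 20).
#' @param setSize disease-set size (default 50).
#' @param baseSeed first seed; replicate s uses `baseSeed + s - 1`.
#' @param alpha group-test level (default 0.05).
#' @return list: `ks` (pooled KS statistic), `typeI` (group rejection
#'   rate), `nGroups` (total groups tested), `nPooled`.
#' @export
studyNullCalibration <- function(nSeeds = 20, nCells = 2000, nGenes = 1000,
                                 B = 200, nGroups = 20, setSize = 50,
                                 baseSeed = 1, alpha = 0.05) {
  pooledP <- vector("list", nSeeds)
  rejections <- 0L
  for (s in seq_len(nSeeds)) {
    cfg <- nullSimConfig(nGenes, nCells, setSize, seed = baseSeed + s - 1)
    sim <- simulateCounts(cfg)
    sce <- normalizeLog1p(sim$sce)
    scores <- scoreDiseaseSet(sce, sim$truth, B,
                              seed = baseSeed + 10000L + s)
    pooledP[[s]] <- scores@pval
    groups <- rep(seq_len(nGroups), length.out = nCells)
    assoc <- groupAssociation(scores, as.character(groups))
    rejections <- rejections + sum(assoc$p <= alpha)
  }
  p <- unlist(pooledP)
  list(ks = unname(suppressWarnings(ks.test(p, "punif")$statistic)),
       typeI = rejections / (nSeeds * nGroups),
       nGroups = nSeeds * nGroups, nPooled = length(p))
}

nullSimConfig <- function(nGenes, nCells, setSize, seed,
                          diseaseFold = 1) {
  simConfig(nGenes = nGenes, nCells = nCells,
            cellTypes = c(all = 1), nMarkersPerType = 0,
            diseaseSetSize = setSize, diseaseFold = diseaseFold,
            affected = data.frame(cell_type = "all", fraction = 0.2),
            nLocusGenes = setSize, nUndetectedLocusGenes = 0,
            nCoregBystanders = 0, moduleSizes = integer(0),
            moduleTadCounts = integer(0), nOutsideHits = 0,
            nTads = 5, seed = seed)
}

# Score the planted disease set of a simulation: detected-gene filter,
# bins, matched controls, scoring.
scoreDiseaseSet <- function(sce, truth, B, seed, weights = NULL) {
  genes <- truth$genes$gene[truth$genes$disease]
  det <- filterDetectedGenes(genes, sce)$detected
  w <- if (is.null(weights)) rep(1, length(det)) else weights[det]
  set <- WeightedGeneSet(det, w, name = "disease_set")
  bins <- computeGeneBins(sce)
  ctrl <- sampleControlSets(bins, set, B = B, seed = seed)
  scoreCells(sce, set, ctrl)
}

#' Power and heterogeneity contrast of the scoring pipeline
#'
#' Simulations with a 1.5x disease effect carried by 20% of one 300-cell
#' type ("subpop") and by 100% of another ("uniform"): measures how often
#' the group-association test flags the subpopulation type, how often the
#' Geary's C heterogeneity test flags it, and how often the uniformly
#' elevated type is (correctly) not flagged as heterogeneous.
#'
#' @param nSeeds replicate simulations (default 20).
#' @param nGenes genes per simulation (default 2000; coarser transcriptomes
#'   degrade the control-matching bins and with them the test's power).
#' @param typeCells cells in the affected type (default 300).
#' @param nCells total cells (default 2000).
#' @param B control sets (default 200).
#' @param fold disease fold effect (default 1.5).
#' @param baseSeed first seed.
#' @param alpha test level.
#' @return list of rates: `assocPower`, `heteroPowerSubpop`,
#'   `heteroNullUniform`, plus `nSeeds`.
#' @export
studyScoringPower <- function(nSeeds = 20, nGenes = 2000, typeCells = 300,
                              nCells = 2000, B = 200, fold = 1.5,
                              baseSeed = 1, alpha = 0.05) {
  prop <- typeCells / nCells
  rest <- (1 - prop) / 4
  powerCfg <- function(seed, frac) simConfig(
    nGenes = nGenes, nCells = nCells,
    cellTypes = c(target = prop, t2 = rest, t3 = rest, t4 = rest,
                  t5 = rest),
    nMarkersPerType = 60, diseaseSetSize = 87, diseaseFold = fold,
    affected = data.frame(cell_type = "target", fraction = frac),
    nLocusGenes = 87, nUndetectedLocusGenes = 0, nCoregBystanders = 0,
    moduleSizes = integer(0), moduleTadCounts = integer(0),
    nOutsideHits = 0, nTads = 5, seed = seed)
  runScenario <- function(cfg, ctrlSeed) {
    sim <- simulateCounts(cfg)
    sce <- normalizeLog1p(sim$sce)
    scores <- scoreDiseaseSet(sce, sim$truth, B, seed = ctrlSeed)
    labels <- sim$truth$cells$cell_type
    # cell-state embedding for the heterogeneity graph: leave the scored
    # genes out, otherwise the score correlates with graph position
    # through the shared genes and a uniform shift looks structured
    hvgs <- setdiff(selectHVGs(sce, n = min(2000, nGenes)),
                    sim$truth$genes$gene[sim$truth$genes$disease])
    sce <- embedPCA(sce, hvgs, nPcs = 20)
    het <- groupHeterogeneity(scores,
                              SingleCellExperiment::reducedDim(sce, "PCA"),
                              labels)
    list(assocP = groupAssociation(scores, labels),
         hetP = het)
  }
  assocHit <- heteroHit <- uniformOk <- 0L
  for (s in seq_len(nSeeds)) {
    # scenario A: the effect confined to 20% of the target type
    a <- runScenario(powerCfg(baseSeed + s - 1, 0.2),
                     baseSeed + 10000L + s)
    assocHit <- assocHit +
      (a$assocP$p[a$assocP$group == "target"] <= alpha)
    heteroHit <- heteroHit +
      (a$hetP$p[a$hetP$group == "target"] <= alpha)
    # scenario B: the whole target type uniformly elevated
    b <- runScenario(powerCfg(baseSeed + 50000L + s, 1),
                     baseSeed + 60000L + s)
    uniformOk <- uniformOk +
      (b$hetP$p[b$hetP$group == "target"] > alpha)
  }
  list(assocPower = assocHit / nSeeds,
       heteroPowerSubpop = heteroHit / nSeeds,
       heteroNullUniform = uniformOk / nSeeds, nSeeds = nSeeds)
}

#' Recovery of planted differentially expressed genes
#'
#' Simulates two 500-cell groups where planted genes carry a fold effect
#' in one group, runs the rank-sum test with BH correction and measures
#' sensitivity and specificity at the FDR threshold.
#'
#' @param nSeeds replicates (default 5).
#' @param nGenes genes per simulation (default 1000).
#' @param groupSize cells per group (default 500).
#' @param nDe planted DE genes (default 100).
#' @param fold planted fold effect (default 1.5).
#' @param alpha BH threshold (default 0.05).
#' @param baseSeed first seed.
#' @return list: `sensitivity`, `specificity` (means over seeds),
#'   `perSeed` data.frame.
#' @export
studyDegRecovery <- function(nSeeds = 5, nGenes = 1000, groupSize = 500,
                             nDe = 100, fold = 1.5, alpha = 0.05,
                             baseSeed = 1) {
  per <- lapply(seq_len(nSeeds), function(s) {
    cfg <- simConfig(nGenes = nGenes, nCells = 2 * groupSize,
                     cellTypes = c(all = 1), nMarkersPerType = 0,
                     diseaseSetSize = nDe, diseaseFold = fold,
                     affected = data.frame(cell_type = "all",
                                           fraction = 0.5),
                     nLocusGenes = nDe, nUndetectedLocusGenes = 0,
                     nCoregBystanders = 0, moduleSizes = integer(0),
                     moduleTadCounts = integer(0), nOutsideHits = 0,
                     nTads = 5, seed = baseSeed + s - 1)
    sim <- simulateCounts(cfg)
    sce <- normalizeLog1p(sim$sce)
    aff <- sim$truth$cells$affected
    deg <- wilcoxonMarkers(sce, sim$truth$cells$cell[aff],
                           sim$truth$cells$cell[!aff])
    gt <- sim$truth$genes[match(deg$gene, sim$truth$genes$gene), ]
    de <- gt$disease
    trueDe <- de | gt$subpop_marker  # subpop markers are DE at their own fold
    called <- deg$padj < alpha
    data.frame(seed = baseSeed + s - 1,
               sensitivity = mean(called[de] & deg$up[de]),
               specificity = mean(!called[!trueDe]))
  })
  per <- do.call(rbind, per)
  list(sensitivity = mean(per$sensitivity),
       specificity = mean(per$specificity), perSeed = per)
}

#' Planted-module recovery through the network stage
#'
#' Simulates one cell group with five planted 50-gene modules plus noise
#' genes, builds metacells, selects the soft power, detects modules, and
#' compares with truth: adjusted Rand index over gene labels, detected
#' module count, correlation of each planted latent factor with its
#' matched eigengene, and whether the locus-enriched module ranks first by
#' TAD-gene percentage.
#'
#' @param nSeeds replicates (default 5).
#' @param nGenes total genes (default 500: 5 x 50 module + 250 noise).
#' @param nCells cells simulated (default 2000).
#' @param targetN metacells (default 250).
#' @param baseSeed first seed.
#' @return list: `ari`, `nModules`, `factorCor` (mean absolute eigengene
#'   correlation), `tadFirstRate`, `perSeed`.
#' @export
studyModuleRecovery <- function(nSeeds = 5, nGenes = 500, nCells = 2000,
                                targetN = 250, baseSeed = 1) {
  per <- lapply(seq_len(nSeeds), function(s) {
    cfg <- simConfig(nGenes = nGenes, nCells = nCells,
                     cellTypes = c(all = 1), nMarkersPerType = 0,
                     diseaseSetSize = 0, diseaseFold = 1,
                     affected = data.frame(cell_type = "all",
                                           fraction = 0),
                     nLocusGenes = 40, nUndetectedLocusGenes = 0,
                     nCoregBystanders = 0, moduleSizes = rep(50L, 5),
                     moduleLoading = 0.8, moduleActiveType = "all",
                     moduleTadCounts = c(20L, 5L, 3L, 0L, 0L),
                     nOutsideHits = 0, nTads = 10,
                     seed = baseSeed + s - 1)
    sim <- simulateCounts(cfg)
    sce <- normalizeLog1p(sim$sce)
    hvgs <- selectHVGs(sce, n = min(400, nGenes))
    sce <- embedPCA(sce, hvgs, nPcs = 20)
    mc <- buildMetacells(sce, "all", sim$truth$cells$cell_type,
                         targetN = targetN,
                         seed = baseSeed + 20000L + s)
    sp <- selectSoftPower(mc)
    ms <- detectModules(metacellExpr(mc)[sp$genes, , drop = FALSE],
                        sp$power)
    truthMod <- setNames(sim$truth$genes$module, sim$truth$genes$gene)
    lab <- moduleLabels(ms)
    common <- intersect(names(lab), names(truthMod))
    ari <- mclust::adjustedRandIndex(lab[common], truthMod[common])
    nMod <- length(unique(lab[lab > 0]))
    # match detected modules to truth modules by overlap; compare each
    # planted latent factor (averaged over metacell members) with the
    # matched eigengene
    mcFactors <- vapply(seq_len(ncol(metacellExpr(mc))), function(j) {
      cells <- metacellMembers(mc)[[j]]
      colMeans(sim$truth$moduleFactors[cells, , drop = FALSE])
    }, numeric(5))
    eg <- moduleEigengenes(ms)
    fc <- vapply(1:5, function(m) {
      tg <- names(truthMod)[truthMod == m]
      ov <- vapply(moduleGenes(ms), function(g) length(intersect(g, tg)),
                   integer(1))
      if (!length(ov) || max(ov) == 0) return(NA_real_)
      best <- names(ov)[which.max(ov)]
      abs(cor(eg[, best], mcFactors[m, ]))
    }, numeric(1))
    tads <- simulateTads(sim$truth, cfg)
    rank <- rankModulesByTadFraction(ms, tads)
    tg1 <- names(truthMod)[truthMod == 1]
    ov1 <- vapply(moduleGenes(ms), function(g) length(intersect(g, tg1)),
                  integer(1))
    tadFirst <- length(ov1) > 0 &&
      as.integer(rank$module[1]) == as.integer(names(ov1)[which.max(ov1)])
    data.frame(seed = baseSeed + s - 1, ari = ari, nModules = nMod,
               factorCor = mean(fc, na.rm = TRUE),
               tadFirst = tadFirst)
  })
  per <- do.call(rbind, per)
  list(ari = mean(per$ari), nModules = mean(per$nModules),
       factorCor = mean(per$factorCor), tadFirstRate = mean(per$tadFirst),
       perSeed = per)
}

#' Calibration and power of the competitive gene-set test
#'
#' Null replicates (independent standard-normal z-scores) measure the
#' rejection rate at the nominal level; power replicates shift the z of
#' the set genes and measure detection.
#'
#' @param nNull null replicates (default 1000).
#' @param nPower power replicates (default 20).
#' @param nGenes background size (default 2000).
#' @param setSize tested set size (default 50).
#' @param shift z-shift of set genes in power replicates (default 0.5).
#' @param alpha level (default 0.05).
#' @param baseSeed first seed.
#' @return list: `typeI`, `power`, `nNull`, `nPower`.
#' @export
studyCompetitiveTest <- function(nNull = 1000, nPower = 20, nGenes = 2000,
                                 setSize = 50, shift = 0.5, alpha = 0.05,
                                 baseSeed = 1) {
  genes <- sprintf("g%04d", seq_len(nGenes))
  set <- genes[seq_len(setSize)]
  oneRep <- function(seed, sh) {
    set.seed(seed)
    z <- rnorm(nGenes)
    z[seq_len(setSize)] <- z[seq_len(setSize)] + sh
    gwas <- data.frame(gene = genes, z = z,
                       p = pnorm(z, lower.tail = FALSE))
    competitiveGeneSetTest(gwas, set, genes)$p
  }
  nullP <- vapply(seq_len(nNull), function(i)
    oneRep(baseSeed + i - 1, 0), numeric(1))
  powerP <- vapply(seq_len(nPower), function(i)
    oneRep(baseSeed + 100000L + i, shift), numeric(1))
  list(typeI = mean(nullP <= alpha), power = mean(powerP <= alpha),
       nNull = nNull, nPower = nPower)
}

#' End-to-end determinism and planted-candidate recovery
#'
#' Runs the full pipeline at fast-test scale. `determinism`: the same
#' configuration and seed twice must give byte-identical outputs.
#' `recovery`: over several seeds, planted co-regulated bystander genes
#' must surface in the candidate table under the DEG or scDRS-TAD-gene
#' approach and planted outside-locus GWAS hits under the network + GWAS
#' approach.
#'
#' @param nSeeds recovery replicates (default 5).
#' @param baseSeed first seed.
#' @param dir scratch directory for run outputs (default a tempdir).
#' @return list: `identical` (logical), `seedOk` (per-seed success),
#'   `bystanderRecall`, `outsideHitRecall`, `successRate`.
#' @export
studyPipelineEndToEnd <- function(nSeeds = 5, baseSeed = 1,
                                  dir = tempfile("e2e")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d1 <- file.path(dir, "run_a"); d2 <- file.path(dir, "run_b")
  cfg <- runConfig(seed = baseSeed)
  runPipeline(cfg, d1)
  runPipeline(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  same <- identical(f1, list.files(d2, recursive = TRUE)) &&
    all(tools::md5sum(file.path(d1, f1)) ==
        tools::md5sum(file.path(d2, f1)))
  seedOk <- logical(nSeeds)
  bRecall <- oRecall <- numeric(nSeeds)
  for (s in seq_len(nSeeds)) {
    d <- file.path(dir, paste0("seed", s))
    if (s == 1) d <- d1  # reuse the first run
    else runPipeline(runConfig(seed = baseSeed + s - 1), d)
    cand <- read.table(file.path(d, "candidates.tsv"), header = TRUE,
                       sep = "\t")
    truth <- read.table(file.path(d, "inputs", "truth_genes.tsv"),
                        header = TRUE, sep = "\t")
    bys <- truth$gene[truth$bystander]
    hits <- truth$gene[truth$outside_hit]
    bFound <- cand$gene[cand$approach %in% c("DEG", "scDRS-TAD-gene")]
    oFound <- cand$gene[cand$approach == "hdWGCNA+GWAS"]
    bRecall[s] <- mean(bys %in% bFound)
    oRecall[s] <- mean(hits %in% oFound)
    seedOk[s] <- bRecall[s] >= 0.5 && oRecall[s] >= 0.5
  }
  list(identical = same, seedOk = seedOk,
       bystanderRecall = mean(bRecall), outsideHitRecall = mean(oRecall),
       successRate = mean(seedOk))
}
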