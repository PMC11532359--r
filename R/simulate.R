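#' Simulation configuration with planted ground truth
#'
#' Builds the parameter list for the synthetic-data generator. Defaults
#' emulate an embryonic head scRNA-seq subset paired with gene-based GWAS
#' output: five cell types with negative-binomial counts and library-size
#' variation, a disease gene set over-expressed in a fraction of one cell
#' type, co-expressed gene modules driven by cell-level latent factors, a
#' risk-locus annotation whose detected-gene arithmetic mirrors the study
#' scale (404 locus genes, 51 undetected, 87-gene disease set, 45 loci),
#' and gene-level z-scores elevated for planted disease genes.
#'
#' @param nGenes,nCells matrix dimensions.
#' @param cellTypes named numeric of cell-type proportions (sum to 1).
#' @param baselineMeanlog,baselineSdlog log-normal parameters of baseline
#'   per-gene mean counts.
#' @param dispersion negative-binomial size parameter (gene-level).
#' @param libSdlog sdlog of the log-normal per-cell library-size factor.
#' @param nMarkersPerType,markerFold cell-type marker genes and their fold.
#' @param nSubpopMarkers,subpopMarkerFold marker genes of the affected
#'   subpopulation itself: affected cells are a distinct cell state, not
#'   just gene-set over-expressors, so they carry their own expression
#'   program (this is what makes the subpopulation coherent in embedding
#'   space).
#' @param diseaseSetSize number of planted disease genes.
#' @param diseaseFold multiplicative effect of disease genes in affected
#'   cells; 1.0 is the null.
#' @param affected data.frame with columns `cell_type` and `fraction`: which
#'   cell types carry the effect and on what fraction of their cells.
#' @param diseaseExprQuantile disease (and bystander) genes are drawn from
#'   genes whose baseline mean exceeds this quantile — candidate genes are
#'   robustly detected in the relevant tissue.
#' @param nLocusGenes total genes inside risk loci (including undetected).
#' @param nUndetectedLocusGenes locus genes absent from the count matrix.
#' @param nCoregBystanders locus genes outside the disease set that share
#'   the disease effect (co-regulated candidates the pipeline should find).
#' @param moduleSizes integer vector of planted module sizes.
#' @param moduleLoading latent-factor loading of module genes.
#' @param moduleActiveType cell type(s) in which module factors are active.
#' @param moduleTadCounts per-module count of locus genes planted inside
#'   the module (drives TAD-fraction ranking).
#' @param nOutsideHits module genes outside any locus with elevated z-score
#'   (the network + GWAS candidates).
#' @param gwasShift z-score shift of disease genes and outside hits.
#' @param nTads number of risk loci.
#' @param seed master seed; every draw is reproducible from it.
#' @return A validated list of class `simConfig`.
#' @export
simConfig <- function(nGenes = 5000, nCells = 3000,
                      cellTypes = c(epithelium = 0.3, mesenchyme = 0.25,
                                    neurons = 0.2, endothelium = 0.15,
                                    blood = 0.1),
                      baselineMeanlog = log(0.3), baselineSdlog = 1.2,
                      dispersion = 2, libSdlog = 0.3,
                      nMarkersPerType = 100, markerFold = 3,
                      nSubpopMarkers = 60, subpopMarkerFold = 5,
                      diseaseSetSize = 87, diseaseFold = 1.5,
                      affected = data.frame(cell_type = "epithelium",
                                            fraction = 0.2),
                      diseaseExprQuantile = 0.5,
                      nLocusGenes = 404, nUndetectedLocusGenes = 51,
                      nCoregBystanders = 10,
                      moduleSizes = rep(50L, 5), moduleLoading = 0.8,
                      moduleActiveType = "epithelium",
                      moduleTadCounts = c(15, 5, 3, 0, 0),
                      nOutsideHits = 4, gwasShift = 4,
                      nTads = 45, seed = 1) {
  cfg <- list(nGenes = as.integer(nGenes), nCells = as.integer(nCells),
              cellTypes = cellTypes, baselineMeanlog = baselineMeanlog,
              baselineSdlog = baselineSdlog, dispersion = dispersion,
              libSdlog = libSdlog, nMarkersPerType = as.integer(nMarkersPerType),
              markerFold = markerFold,
              nSubpopMarkers = as.integer(nSubpopMarkers),
              subpopMarkerFold = subpopMarkerFold,
              diseaseSetSize = as.integer(diseaseSetSize),
              diseaseFold = diseaseFold, affected = affected,
              diseaseExprQuantile = diseaseExprQuantile,
              nLocusGenes = as.integer(nLocusGenes),
              nUndetectedLocusGenes = as.integer(nUndetectedLocusGenes),
              nCoregBystanders = as.integer(nCoregBystanders),
              moduleSizes = as.integer(moduleSizes),
              moduleLoading = moduleLoading,
              moduleActiveType = moduleActiveType,
              moduleTadCounts = as.integer(moduleTadCounts),
              nOutsideHits = as.integer(nOutsideHits),
              gwasShift = gwasShift, nTads = as.integer(nTads),
              seed = as.integer(seed))
  class(cfg) <- "simConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  if (abs(sum(cfg$cellTypes) - 1) > 1e-8)
    stop("config error: cell-type proportions must sum to 1")
  if (is.null(names(cfg$cellTypes)))
    stop("config error: cell types must be named")
  if (any(cfg$affected$fraction < 0 | cfg$affected$fraction > 1))
    stop("config error: affected fractions must lie in [0, 1]")
  if (!all(cfg$affected$cell_type %in% names(cfg$cellTypes)))
    stop("config error: affected cell type not among cell types")
  if (cfg$diseaseFold <= 0) stop("config error: fold-effect must be > 0")
  if (sum(cfg$moduleSizes) > cfg$nGenes)
    stop("config error: module sizes exceed the number of genes")
  if (length(cfg$moduleTadCounts) != length(cfg$moduleSizes))
    stop("config error: moduleTadCounts must align with moduleSizes")
  if (any(cfg$moduleTadCounts > cfg$moduleSizes))
    stop("config error: moduleTadCounts cannot exceed module sizes")
  if (length(cfg$moduleSizes) &&
      !any(cfg$moduleActiveType %in% names(cfg$cellTypes)))
    stop("config error: moduleActiveType must name an existing cell type")
  nDetLocus <- cfg$nLocusGenes - cfg$nUndetectedLocusGenes
  if (nDetLocus < cfg$diseaseSetSize + cfg$nCoregBystanders)
    stop("config error: locus genes cannot hold disease set + bystanders")
  if (cfg$diseaseSetSize + cfg$nCoregBystanders + nDetLocus +
      sum(cfg$moduleSizes) > cfg$nGenes)
    stop("config error: planted roles exceed the number of genes")
  invisible(cfg)
}

#' Simulate a single-cell count matrix with planted structure
#'
#' Counts are negative binomial with mean
#' `baseline x type-marker fold x module-factor multiplier x disease fold x
#' library size` and gene-level dispersion. Disease (and co-regulated
#' bystander) genes are multiplied by the fold-effect only in affected
#' cells; module genes share a per-cell Gaussian latent factor entering the
#' mean log-additively (`exp(loading * z - loading^2 / 2)`, mean-preserving),
#' active only in the configured cell types.
#'
#' @param config a [simConfig()] list.
#' @return list with `sce` (a `SingleCellExperiment`, counts + colData
#'   `sample`/`cell_type`) and `truth` (per-cell and per-gene ground truth
#'   plus the module latent-factor matrix).
#' @export
simulateCounts <- function(config) {
  cfg <- validateSimConfig(config)
  set.seed(cfg$seed)
  nG <- cfg$nGenes; nC <- cfg$nCells
  geneNames <- sprintf("gene%05d", seq_len(nG))
  cellNames <- sprintf("cell%05d", seq_len(nC))

  baseMean <- rlnorm(nG, cfg$baselineMeanlog, cfg$baselineSdlog)

  # --- gene roles ---------------------------------------------------------
  hiExpr <- which(baseMean > quantile(baseMean, cfg$diseaseExprQuantile))
  disease <- sample(hiExpr, cfg$diseaseSetSize)
  bystander <- sample(setdiff(hiExpr, disease), cfg$nCoregBystanders)
  nPlainLocus <- cfg$nLocusGenes - cfg$nUndetectedLocusGenes -
    cfg$diseaseSetSize - cfg$nCoregBystanders
  free <- setdiff(seq_len(nG), c(disease, bystander))
  plainLocus <- sample(free, nPlainLocus)
  free <- setdiff(free, plainLocus)

  nMod <- length(cfg$moduleSizes)
  moduleOf <- integer(nG)
  locusPool <- plainLocus
  for (m in seq_len(nMod)) {
    fromLocus <- if (cfg$moduleTadCounts[m] > 0)
      sample(locusPool, cfg$moduleTadCounts[m]) else integer(0)
    locusPool <- setdiff(locusPool, fromLocus)
    fromFree <- sample(free, cfg$moduleSizes[m] - length(fromLocus))
    free <- setdiff(free, fromFree)
    moduleOf[c(fromLocus, fromFree)] <- m
  }
  outsideHits <- integer(0)
  if (cfg$nOutsideHits > 0) {
    eligible <- which(moduleOf > 0 &
                      !seq_len(nG) %in% c(plainLocus, disease, bystander))
    # place hits in the two most locus-enriched planted modules: those are
    # the ones the TAD-fraction ranking reliably selects (alongside the
    # emergent disease-state module)
    selMods <- order(cfg$moduleTadCounts / cfg$moduleSizes,
                     decreasing = TRUE)[seq_len(min(2, nMod))]
    for (i in seq_len(cfg$nOutsideHits)) {
      m <- selMods[(i - 1) %% length(selMods) + 1]
      pool <- setdiff(eligible[moduleOf[eligible] == m], outsideHits)
      outsideHits <- c(outsideHits, sample(pool, 1))
    }
  }

  # --- cell structure -----------------------------------------------------
  typeNames <- names(cfg$cellTypes)
  sizes <- diff(round(cumsum(c(0, cfg$cellTypes)) * nC))
  cellType <- rep(typeNames, sizes)
  libFactor <- rlnorm(nC, 0, cfg$libSdlog)

  markerMult <- matrix(1, nG, length(typeNames),
                       dimnames = list(NULL, typeNames))
  markerPool <- setdiff(seq_len(nG), c(disease, bystander))
  for (t in typeNames) {
    mk <- sample(markerPool, cfg$nMarkersPerType)
    markerPool <- setdiff(markerPool, mk)
    markerMult[mk, t] <- cfg$markerFold
  }
  # subpopulation markers are specifically expressed: near-off outside the
  # affected state (below-median baseline), induced within it
  loPool <- intersect(markerPool,
                      which(baseMean <= quantile(baseMean,
                                                 cfg$diseaseExprQuantile)))
  subpopMarkers <- if (cfg$nSubpopMarkers > 0)
    sample(loPool, cfg$nSubpopMarkers) else integer(0)

  affectedFlag <- logical(nC)
  for (i in seq_len(nrow(cfg$affected))) {
    idx <- which(cellType == cfg$affected$cell_type[i])
    nAff <- round(length(idx) * cfg$affected$fraction[i])
    if (nAff > 0) affectedFlag[sample(idx, nAff)] <- TRUE
  }

  modActive <- matrix(0, nC, nMod)
  factors <- matrix(0, nC, nMod)
  if (nMod > 0) {
    activeCells <- cellType %in% cfg$moduleActiveType
    factors[activeCells, ] <- rnorm(sum(activeCells) * nMod)
    modActive[activeCells, ] <- 1
  }

  L <- cfg$moduleLoading

  # --- draw counts in cell blocks ----------------------------------------
  blocks <- split(seq_len(nC), ceiling(seq_len(nC) / 500))
  parts <- lapply(blocks, function(cells) {
    mu <- baseMean * markerMult[, cellType[cells], drop = FALSE]
    for (m in seq_len(nMod)) {
      gm <- moduleOf == m
      f <- exp(L * factors[cells, m] - L^2 / 2)
      mu[gm, ] <- mu[gm, ] %*% diag(f, nrow = length(f))
    }
    aff <- affectedFlag[cells]
    if (any(aff) && cfg$diseaseFold != 1) {
      mu[disease, aff] <- mu[disease, aff] * cfg$diseaseFold
      # bystanders and subpopulation markers belong to the affected cell
      # state's expression program; under the null (fold 1) no such state
      # exists and the affected flag must stay distributionally inert
      stateGenes <- c(bystander, subpopMarkers)
      if (length(stateGenes) && cfg$subpopMarkerFold != 1)
        mu[stateGenes, aff] <- mu[stateGenes, aff] * cfg$subpopMarkerFold
    }
    mu <- mu %*% diag(libFactor[cells], nrow = length(cells))
    cnt <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                          size = cfg$dispersion), nrow = nG)
    methods::as(Matrix::Matrix(cnt, sparse = TRUE), "CsparseMatrix")
  })
  counts <- do.call(cbind, parts)
  dimnames(counts) <- list(geneNames, cellNames)

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(sample = "S1", cell_type = cellType,
                                   row.names = cellNames))

  undetNames <- if (cfg$nUndetectedLocusGenes > 0)
    sprintf("geneU%04d", seq_len(cfg$nUndetectedLocusGenes)) else character(0)
  geneTruth <- data.frame(
    gene = c(geneNames, undetNames),
    detected = c(rep(TRUE, nG), rep(FALSE, length(undetNames))),
    baseline_mean = c(baseMean, rep(NA_real_, length(undetNames))),
    module = c(moduleOf, rep(0L, length(undetNames))),
    disease = c(seq_len(nG) %in% disease, rep(FALSE, length(undetNames))),
    bystander = c(seq_len(nG) %in% bystander, rep(FALSE, length(undetNames))),
    locus_gene = c(seq_len(nG) %in% c(disease, bystander, plainLocus),
                   rep(TRUE, length(undetNames))),
    subpop_marker = c(seq_len(nG) %in% subpopMarkers,
                      rep(FALSE, length(undetNames))),
    outside_hit = c(seq_len(nG) %in% outsideHits,
                    rep(FALSE, length(undetNames))),
    stringsAsFactors = FALSE)
  cellTruth <- data.frame(cell = cellNames, cell_type = cellType,
                          affected = affectedFlag, stringsAsFactors = FALSE)
  rownames(factors) <- cellNames
  list(sce = sce,
       truth = list(cells = cellTruth, genes = geneTruth,
                    moduleFactors = factors))
}

#' Simulate a gene-based GWAS table
#'
#' Null genes receive `z ~ N(0, 1)`; planted disease genes and outside-locus
#' module hits are shifted by `gwasShift`. `p` is the one-sided upper-tail
#' normal probability of `z`. A `log_length` covariate (log gene-length
#' proxy, independent of z) is included for competitive gene-set testing.
#'
#' @param truth the `truth` component of [simulateCounts()].
#' @param config the same [simConfig()].
#' @return data.frame with columns `gene`, `z`, `p`, `log_length`.
#' @export
simulateGwas <- function(truth, config) {
  set.seed(config$seed + 1000L)
  gt <- truth$genes
  z <- rnorm(nrow(gt))
  z[gt$disease | gt$bystander | gt$outside_hit] <-
    z[gt$disease | gt$bystander | gt$outside_hit] + config$gwasShift
  data.frame(gene = gt$gene, z = z, p = pnorm(z, lower.tail = FALSE),
             log_length = rnorm(nrow(gt), 10, 1), stringsAsFactors = FALSE)
}

#' Simulate a risk-locus (TAD) annotation
#'
#' Emits `nTads` genomic loci and assigns every locus-flagged gene of the
#' truth table (disease set, bystanders, plain locus genes and undetected
#' locus genes) to a random locus.
#'
#' @param truth the `truth` component of [simulateCounts()].
#' @param config the same [simConfig()].
#' @return A [TadAnnotation-class].
#' @export
simulateTads <- function(truth, config) {
  set.seed(config$seed + 2000L)
  n <- config$nTads
  ids <- sprintf("L%03d", seq_len(n))
  chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
  start <- sample.int(2e8, n)
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = start,
                     width = sample(5e5:2e6, n, replace = TRUE)))
  gr$locus_id <- ids
  locusGenes <- truth$genes$gene[truth$genes$locus_gene]
  geneMap <- setNames(ids[sample.int(n, length(locusGenes), replace = TRUE)],
                      locusGenes)
  TadAnnotation(gr, geneMap)
}

#' Simulate a term-to-gene map for enrichment testing
#'
#' One term per planted module (a fraction of the module's genes plus
#' random padding) and additional random terms.
#'
#' @param truth the `truth` component of [simulateCounts()].
#' @param config the same [simConfig()].
#' @param moduleFraction fraction of each module's genes in its term.
#' @param nRandomTerms,randomTermSize random-term count and size.
#' @return named list of [WeightedGeneSet-class] objects.
#' @export
simulateTermMap <- function(truth, config, moduleFraction = 0.7,
                            nRandomTerms = 20, randomTermSize = 50) {
  set.seed(config$seed + 3000L)
  gt <- truth$genes[truth$genes$detected, ]
  sets <- list()
  for (m in seq_along(config$moduleSizes)) {
    mg <- gt$gene[gt$module == m]
    pick <- sample(mg, max(1, round(length(mg) * moduleFraction)))
    pad <- sample(setdiff(gt$gene, mg), 10)
    sets[[sprintf("TERM_MOD%d", m)]] <-
      WeightedGeneSet(c(pick, pad), name = sprintf("TERM_MOD%d", m))
  }
  for (i in seq_len(nRandomTerms)) {
    nm <- sprintf("TERM_RAND%02d", i)
    sets[[nm]] <- WeightedGeneSet(sample(gt$gene, randomTermSize), name = nm)
  }
  sets
}
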