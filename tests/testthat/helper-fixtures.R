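# Small in-code fixtures shared across test files.

# SingleCellExperiment from a dense count matrix (genes x cells).
makeSce <- function(counts, cellType = NULL, sample = "S1") {
  counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  n <- ncol(counts)
  cd <- S4Vectors::DataFrame(
    sample = rep(sample, length.out = n),
    cell_type = rep(if (is.null(cellType)) "all" else cellType,
                    length.out = n),
    row.names = colnames(counts))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    colData = cd)
}

# SCE with a prescribed logcounts layer (for formula-level score tests).
makeNormalizedSce <- function(logcounts) {
  logcounts <- as.matrix(logcounts)
  if (is.null(rownames(logcounts)))
    rownames(logcounts) <- sprintf("g%03d", seq_len(nrow(logcounts)))
  if (is.null(colnames(logcounts)))
    colnames(logcounts) <- sprintf("c%03d", seq_len(ncol(logcounts)))
  counts <- methods::as(Matrix::Matrix(ceiling(expm1(logcounts)),
                                       sparse = TRUE), "CsparseMatrix")
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts,
                  logcounts = methods::as(Matrix::Matrix(logcounts,
                                                         sparse = TRUE),
                                          "CsparseMatrix")))
}

# Random count SCE for property-style checks.
randomSce <- function(nGenes = 50, nCells = 40, seed = 1, mu = 2) {
  set.seed(seed)
  makeSce(matrix(rnbinom(nGenes * nCells, mu = mu, size = 2), nGenes))
}

# A tiny TadAnnotation.
makeTads <- function(geneMap, nLoci = max(1, length(unique(geneMap)))) {
  ids <- unique(c(geneMap, paste0("L", seq_len(nLoci))))
  gr <- GenomicRanges::GRanges(
    rep("chr1", length(ids)),
    IRanges::IRanges(start = seq_along(ids) * 1000, width = 500))
  gr$locus_id <- ids
  TadAnnotation(gr, geneMap)
}

# CellScores with prescribed values (for group-test unit checks).
makeScores <- function(normalized, controls, pval = NULL) {
  n <- length(normalized)
  cells <- sprintf("c%03d", seq_len(n))
  if (is.null(pval)) pval <- rep(0.5, n)
  new("CellScores", cells = cells, raw = normalized,
      normalized = normalized, pval = pval,
      fdr = p.adjust(pval, "BH"), controls = as.matrix(controls))
}
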