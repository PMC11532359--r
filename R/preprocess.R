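#' Depth-normalize and log-transform counts
#'
#' Adds a `logcounts` assay with
#' `value(g, c) = ln(1 + count(g, c) / total(c) * scale)`. Cells with zero
#' total count stay all-zero (with a warning). Per-cell totals are stored
#' in `colData(sce)$total_counts`.
#'
#' @param sce `SingleCellExperiment` with a `counts` assay.
#' @param scale depth-scaling constant (default 1e4).
#' @return The `SingleCellExperiment` with a `logcounts` assay added.
#' @export
normalizeLog1p <- function(sce, scale = 1e4) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0))
    warning(sum(tot == 0), " cell(s) with zero total count left all-zero")
  sf <- ifelse(tot == 0, 1, tot / scale)
  norm <- counts %*% Matrix::Diagonal(x = 1 / sf)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "logcounts") <- norm
  SummarizedExperiment::colData(sce)$total_counts <- tot
  S4Vectors::metadata(sce)$log1p_scale <- scale
  sce
}

#' Select highly variable genes by standardized variance
#'
#' Variance-stabilizing selection: a loess fit of log10 variance on log10
#' mean of the raw counts predicts each gene's expected standard deviation;
#' counts are standardized with it, clipped at `sqrt(n_cells)`, and genes
#' are ranked by the variance of the clipped standardized counts.
#'
#' @param sce normalized `SingleCellExperiment` (counts assay used).
#' @param n number of genes to select (default 2000).
#' @param span loess span of the mean-variance fit.
#' @return Character vector of the `n` top-ranked gene identifiers.
#' @export
selectHVGs <- function(sce, n = 2000, span = 0.3) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  nc <- ncol(counts)
  mu <- Matrix::rowMeans(counts)
  v <- rowVarsSparse(counts, mu)
  expressed <- which(v > 0)
  if (n > length(expressed)) {
    warning("requested ", n, " HVGs but only ", length(expressed),
            " expressed genes; returning all")
    n <- length(expressed)
  }
  sdExp <- rep(Inf, length(mu))
  if (length(expressed) >= 30) {
    fit <- loess(log10(v[expressed]) ~ log10(mu[expressed]), span = span,
                 degree = 2)
    sdExp[expressed] <- sqrt(10^predict(fit))
  } else {
    # too few points for a stable local fit: fall back to a global trend
    fit <- lm(log10(v[expressed]) ~ log10(mu[expressed]))
    sdExp[expressed] <- sqrt(10^stats::fitted(fit))
  }
  clipMax <- sqrt(nc)
  # variance of clipped standardized counts, sparse-aware: zeros contribute
  # (-mu/sd)^2 each; nonzeros are clipped at clipMax.
  stdVar <- numeric(length(mu))
  cm <- methods::as(counts, "CsparseMatrix")
  gi <- cm@i + 1L
  x <- cm@x
  z <- (x - mu[gi]) / sdExp[gi]
  z <- pmin(z, clipMax)
  zz <- z^2 - ((0 - mu[gi]) / sdExp[gi])^2  # correction vs all-zero baseline
  sumCorr <- rowsumTapply(zz, gi, length(mu))
  nnz <- rowsumTapply(rep(1, length(gi)), gi, length(mu))
  zeroTerm <- (mu / sdExp)^2 * nc
  zMean <- (rowsumTapply(z, gi, length(mu)) +
            (-mu / sdExp) * (nc - nnz)) / nc
  stdVar[expressed] <- ((zeroTerm + sumCorr)[expressed] -
                        nc * zMean[expressed]^2) / (nc - 1)
  ord <- order(-stdVar, seq_along(stdVar))
  rownames(sce)[ord[seq_len(n)]]
}

rowVarsSparse <- function(m, mu = Matrix::rowMeans(m)) {
  cm <- methods::as(m, "CsparseMatrix")
  sq <- rowsumTapply(cm@x^2, cm@i + 1L, nrow(m))
  (sq - ncol(m) * mu^2) / (ncol(m) - 1)
}

rowsumTapply <- function(x, i, n) {
  out <- numeric(n)
  s <- rowsum(x, i)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Principal-component embedding on scaled highly variable genes
#'
#' Genes are centered and unit-scaled across cells (values clipped at +/-
#' 10) before PCA. A deterministic sign convention makes the
#' largest-magnitude gene loading of each component positive. The result is
#' stored in `reducedDim(sce, "PCA")` with per-component explained variance
#' in its `varExplained` attribute and the HVG list in `metadata`.
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param hvgs gene identifiers to embed on (subset of `rownames(sce)`).
#' @param nPcs number of components (default 30).
#' @param clip absolute cap for scaled values.
#' @return The `SingleCellExperiment` with the `"PCA"` reducedDim set.
#' @export
embedPCA <- function(sce, hvgs, nPcs = 30, clip = 10) {
  if (!all(hvgs %in% rownames(sce)))
    stop("HVGs absent from the matrix: ",
         paste(head(setdiff(hvgs, rownames(sce))), collapse = ", "))
  if (nPcs > min(length(hvgs), ncol(sce)))
    stop("nPcs exceeds min(genes, cells)")
  x <- as.matrix(SummarizedExperiment::assay(sce, "logcounts")[hvgs, ,
                                                               drop = FALSE])
  mu <- rowMeans(x)
  sd <- apply(x, 1, sd)
  sd[sd == 0] <- 1
  xs <- (x - mu) / sd
  xs[xs > clip] <- clip
  xs[xs < -clip] <- -clip
  pc <- prcomp(t(xs), center = FALSE, scale. = FALSE, rank. = nPcs)
  flip <- vapply(seq_len(nPcs), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  emb <- sweep(pc$x[, seq_len(nPcs), drop = FALSE], 2, flip, `*`)
  colnames(emb) <- paste0("PC", seq_len(nPcs))
  rownames(emb) <- colnames(sce)
  attr(emb, "varExplained") <- pc$sdev[seq_len(nPcs)]^2
  attr(emb, "hvgs") <- hvgs
  SingleCellExperiment::reducedDim(sce, "PCA") <- emb
  sce
}

# k nearest neighbors (excluding self) by Euclidean distance, computed in
# row blocks; ties broken by index for determinism.
knnIndex <- function(x, k, blockSize = 1024L) {
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of points")
  sq <- rowSums(x^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = blockSize)) {
    rows <- start:min(start + blockSize - 1L, n)
    d2 <- outer(sq[rows], sq, `+`) - 2 * tcrossprod(x[rows, , drop = FALSE], x)
    for (r in seq_along(rows)) {
      d <- d2[r, ]
      d[rows[r]] <- Inf
      out[rows[r], ] <- order(d)[seq_len(k)]
    }
  }
  out
}

#' Shared-nearest-neighbor Louvain clustering
#'
#' Builds the k-nearest-neighbor graph on the PCA embedding, weights edges
#' by the Jaccard overlap of neighbor sets (each cell's set includes
#' itself), prunes weights below `pruneBelow`, and runs Louvain modularity
#' optimization at the given resolution. Labels are 0-based and ordered by
#' decreasing cluster size.
#'
#' @param sce `SingleCellExperiment` with a `"PCA"` reducedDim, or a
#'   numeric embedding matrix (cells x dims).
#' @param kNeighbors neighbors per cell (default 20).
#' @param resolution Louvain resolution parameter.
#' @param pruneBelow Jaccard pruning threshold (default 1/15).
#' @param seed RNG seed for Louvain.
#' @return Integer vector of cluster labels (0..K-1), named by cell.
#' @export
clusterCells <- function(sce, kNeighbors = 20, resolution = 1,
                         pruneBelow = 1 / 15, seed = 0) {
  emb <- if (is.matrix(sce)) sce else
    SingleCellExperiment::reducedDim(sce, "PCA")
  n <- nrow(emb)
  if (kNeighbors >= n) stop("kNeighbors must be below the number of cells")
  nn <- knnIndex(emb, kNeighbors)
  sets <- cbind(seq_len(n), nn)           # neighbor set includes self
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(sets)),
                              j = as.vector(sets), x = 1, dims = c(n, n))
  shared <- methods::as(Matrix::tcrossprod(adj), "TsparseMatrix")
  setSize <- kNeighbors + 1
  ii <- shared@i + 1L; jj <- shared@j + 1L; s <- shared@x
  upper <- ii < jj
  ii <- ii[upper]; jj <- jj[upper]; s <- s[upper]
  jac <- s / (2 * setSize - s)
  keep <- jac >= pruneBelow
  g <- igraph::graph_from_data_frame(
    data.frame(from = ii[keep], to = jj[keep], weight = jac[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)[as.character(seq_len(n))]
  sz <- sort(table(memb), decreasing = TRUE)
  relab <- setNames(seq_along(sz) - 1L, names(sz))
  labels <- unname(relab[as.character(memb)])
  names(labels) <- rownames(emb)
  labels
}

#' Rank-sum differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test per gene on log-normalized expression,
#' with exact enumeration when both groups have at most `exactMax` cells
#' and a tie-corrected normal approximation (with continuity correction)
#' otherwise. The log2 fold change is computed on depth-normalized means:
#' `log2((mean(expm1(A)) + eps) / (mean(expm1(B)) + eps))`.
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param cellsA,cellsB cell identifiers (or logical/integer indices) of the
#'   two groups; must be non-empty and disjoint.
#' @param genes genes to test (default all).
#' @param exactMax exact-path group-size bound (default 8).
#' @param eps pseudocount on depth-normalized means (default 1e-9).
#' @return data.frame: gene, log2fc, p, padj (BH), meanA, meanB, up
#'   (direction flag, `log2fc > 0`).
#' @export
wilcoxonMarkers <- function(sce, cellsA, cellsB, genes = rownames(sce),
                            exactMax = 8, eps = 1e-9) {
  x <- SummarizedExperiment::assay(sce, "logcounts")
  a <- as.matrix(x[genes, cellsA, drop = FALSE])
  b <- as.matrix(x[genes, cellsB, drop = FALSE])
  nA <- ncol(a); nB <- ncol(b)
  if (nA == 0 || nB == 0) stop("both groups must be non-empty")
  p <- if (nA <= exactMax && nB <= exactMax)
    apply(cbind(a, b), 1, function(v) wilcoxExactP(v[1:nA], v[-(1:nA)]))
  else wilcoxApproxP(a, b)
  meanA <- rowMeans(expm1(a))
  meanB <- rowMeans(expm1(b))
  log2fc <- log2((meanA + eps) / (meanB + eps))
  data.frame(gene = genes, log2fc = log2fc, p = p,
             padj = p.adjust(p, "BH"), meanA = meanA, meanB = meanB,
             up = log2fc > 0, row.names = NULL)
}

# Exact two-sided rank-sum p by enumeration over all C(nA+nB, nA)
# assignments; handles ties exactly.
wilcoxExactP <- function(a, b) {
  nA <- length(a); n <- nA + length(b)
  r <- rank(c(a, b))
  wObs <- sum(r[seq_len(nA)])
  combos <- combn(n, nA)
  w <- colSums(matrix(r[combos], nrow = nA))
  mu <- nA * (n + 1) / 2
  mean(abs(w - mu) >= abs(wObs - mu) - 1e-9)
}

# Vectorized tie-corrected normal approximation over genes (rows).
wilcoxApproxP <- function(a, b) {
  nA <- ncol(a); nB <- ncol(b); n <- nA + nB
  m <- cbind(a, b)
  p <- numeric(nrow(m))
  for (g in seq_len(nrow(m))) {
    r <- rank(m[g, ])
    w <- sum(r[seq_len(nA)])
    ties <- table(m[g, ])
    tieCorr <- sum(ties^3 - ties)
    sigma2 <- nA * nB / 12 * ((n + 1) - tieCorr / (n * (n - 1)))
    if (sigma2 <= 0) { p[g] <- 1; next }
    z <- w - nA * (n + 1) / 2
    corr <- sign(z) * 0.5
    p[g] <- min(1, 2 * pnorm(abs(z - corr) / sqrt(sigma2),
                             lower.tail = FALSE))
  }
  p
}
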