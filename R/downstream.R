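#' Cell-group disease association by Monte Carlo
#'
#' The group statistic is the mean normalized score over the group's cells;
#' the one-sided Monte Carlo p-value compares it with the mean of each
#' control set's normalized scores over the same cells:
#' `p = (1 + #{b: ctrl_b >= stat}) / (1 + B)`.
#'
#' @param scores a [CellScores-class].
#' @param labels group label per scored cell (character/factor), in cell
#'   order or named by cell.
#' @param minCells groups smaller than this are flagged unreliable.
#' @return data.frame: group, n_cells, mean_score, p, reliable.
#' @export
groupAssociation <- function(scores, labels, minCells = 20) {
  labels <- alignLabels(scores, labels)
  ctrl <- controlScores(scores)
  B <- ncol(ctrl)
  norm <- scores@normalized
  groups <- sort(unique(as.character(labels)))
  res <- lapply(groups, function(g) {
    idx <- which(labels == g)
    stat <- mean(norm[idx])
    ctrlMeans <- colMeans(ctrl[idx, , drop = FALSE])
    p <- (1 + sum(ctrlMeans >= stat)) / (1 + B)
    data.frame(group = g, n_cells = length(idx), mean_score = stat,
               p = p, reliable = length(idx) >= minCells)
  })
  out <- do.call(rbind, res)
  if (any(!out$reliable))
    warning("group(s) below ", minCells, " cells; p flagged unreliable: ",
            paste(out$group[!out$reliable], collapse = ", "))
  out
}

alignLabels <- function(scores, labels) {
  if (!is.null(names(labels))) {
    if (!all(scores@cells %in% names(labels)))
      stop("every scored cell must be labeled")
    labels <- labels[scores@cells]
  }
  if (length(labels) != length(scores@cells))
    stop("labels must cover every scored cell")
  as.character(labels)
}

#' Geary's C graph autocorrelation
#'
#' `C = (n - 1) * sum_ij a_ij (x_i - x_j)^2 / (2 * W * sum_i (x_i - xbar)^2)`
#' over an undirected weighted graph given as an edge list (each edge once);
#' `W` is the total edge weight. Values below 1 indicate positive spatial
#' autocorrelation; the heterogeneity statistic reported downstream is
#' `1 - C`.
#'
#' @param x numeric vector of node values.
#' @param edges two-column integer matrix of node index pairs.
#' @param w edge weights (default 1).
#' @return Geary's C (NA when `x` is constant).
#' @export
gearyC <- function(x, edges, w = rep(1, nrow(edges))) {
  n <- length(x)
  ss <- sum((x - mean(x))^2)
  if (ss == 0) return(NA_real_)
  num <- sum(w * (x[edges[, 1]] - x[edges[, 2]])^2)
  (n - 1) * num / (2 * sum(w) * ss)
}

#' Within-group score heterogeneity by Geary's C
#'
#' For each group, a k-nearest-neighbor graph (symmetrized by union) is
#' built on the embedding restricted to the group's cells, and the
#' heterogeneity statistic `1 - C` of the normalized scores is compared
#' with the same statistic of each control set's normalized scores
#' (one-sided Monte Carlo: observed >= control).
#'
#' @param scores a [CellScores-class].
#' @param embedding cells x dims matrix (e.g. `reducedDim(sce, "PCA")`),
#'   rows aligned with or named by the scored cells.
#' @param labels group label per scored cell.
#' @param kNeighbors neighbors per cell within the group (default 15).
#' @param minCells groups must exceed `kNeighbors` cells; smaller groups
#'   get NA.
#' @return data.frame: group, n_cells, one_minus_C, p.
#' @export
groupHeterogeneity <- function(scores, embedding, labels, kNeighbors = 15,
                               minCells = 20) {
  labels <- alignLabels(scores, labels)
  if (!is.null(rownames(embedding)))
    embedding <- embedding[scores@cells, , drop = FALSE]
  ctrl <- controlScores(scores)
  B <- ncol(ctrl)
  norm <- scores@normalized
  groups <- sort(unique(labels))
  res <- lapply(groups, function(g) {
    idx <- which(labels == g)
    n <- length(idx)
    if (n <= kNeighbors || n < minCells)
      return(data.frame(group = g, n_cells = n, one_minus_C = NA_real_,
                        p = NA_real_))
    nn <- knnIndex(embedding[idx, , drop = FALSE], kNeighbors)
    edges <- unique(t(apply(
      cbind(rep(seq_len(n), kNeighbors), as.vector(nn)), 1, sort)))
    x <- norm[idx]
    if (var(x) == 0) {
      warning("group ", g, " has zero score variance; p = 1")
      return(data.frame(group = g, n_cells = n, one_minus_C = NA_real_,
                        p = 1))
    }
    obs <- 1 - gearyC(x, edges)
    xc <- ctrl[idx, , drop = FALSE]
    d2 <- (xc[edges[, 1], , drop = FALSE] - xc[edges[, 2], , drop = FALSE])^2
    num <- colSums(d2)
    ssc <- colSums((xc - matrix(colMeans(xc), n, B, byrow = TRUE))^2)
    cCtrl <- (n - 1) * num / (2 * nrow(edges) * ssc)
    statCtrl <- 1 - cCtrl
    statCtrl[!is.finite(statCtrl)] <- 0
    p <- (1 + sum(statCtrl >= obs)) / (1 + B)
    data.frame(group = g, n_cells = n, one_minus_C = obs, p = p)
  })
  do.call(rbind, res)
}

#' Correlate per-gene expression with per-cell scores
#'
#' Pearson correlation between each gene's log-normalized expression and
#' the cells' normalized disease-relevance scores. Used to prioritize genes
#' outside the tested set whose expression tracks the score.
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param scores a [CellScores-class] over the same cells.
#' @param genes genes to correlate (default all).
#' @return data.frame: gene, r, constant (flag; constant genes get r = 0).
#' @export
correlateScoreWithGenes <- function(sce, scores, genes = rownames(sce)) {
  if (ncol(sce) < 3) stop("need at least 3 cells")
  x <- SummarizedExperiment::assay(sce, "logcounts")[genes, scores@cells,
                                                     drop = FALSE]
  s <- scores@normalized
  n <- length(s)
  sc <- s - mean(s)
  mu <- Matrix::rowMeans(x)
  num <- as.vector(x %*% sc)          # sum x*sc - n*mu*mean(sc=0)
  vx <- rowVarsSparse(x, mu) * (n - 1)
  vs <- sum(sc^2)
  constant <- vx <= 0 | vs <= 0
  r <- ifelse(constant, 0, num / sqrt(pmax(vx, .Machine$double.eps) * vs))
  data.frame(gene = genes, r = r, constant = constant, row.names = NULL)
}

#' Correlation of scores with sequencing depth (QC)
#'
#' Pearson correlation between the normalized score and each cell's total
#' count; values near zero indicate the score is not driven by transcript
#' detection depth.
#'
#' @param scores a [CellScores-class].
#' @param sce `SingleCellExperiment` with a counts assay.
#' @return list with `r` and `defined` (FALSE when depth is constant, in
#'   which case r is reported as 0).
#' @export
qcDepthCorrelation <- function(scores, sce) {
  depth <- Matrix::colSums(
    SummarizedExperiment::assay(sce, "counts"))[scores@cells]
  if (sd(depth) == 0 || sd(scores@normalized) == 0) {
    warning("depth or score vector constant; correlation undefined")
    return(list(r = 0, defined = FALSE))
  }
  list(r = cor(scores@normalized, depth), defined = TRUE)
}

#' Split a cell cluster by score p-value
#'
#' Cells with empirical p <= `pLow` form the associated subcluster, cells
#' with p >= `pHigh` the non-associated subcluster; the remainder are
#' unassigned. With `inclusive = FALSE` the comparisons are strict.
#'
#' @param scores a [CellScores-class].
#' @param clusterCells identifiers of the cluster's cells.
#' @param pLow,pHigh thresholds, `pLow < pHigh`.
#' @param inclusive use `<=` / `>=` (default) rather than `<` / `>`.
#' @return named character vector over `clusterCells` with values
#'   `"associated"`, `"non-associated"` or `"unassigned"`.
#' @export
splitByScore <- function(scores, clusterCells, pLow = 0.01, pHigh = 0.1,
                         inclusive = TRUE) {
  if (pLow >= pHigh) stop("pLow must be below pHigh")
  p <- scorePvals(scores)[clusterCells]
  lab <- rep("unassigned", length(clusterCells))
  if (inclusive) {
    lab[p <= pLow] <- "associated"
    lab[p >= pHigh] <- "non-associated"
  } else {
    lab[p < pLow] <- "associated"
    lab[p > pHigh] <- "non-associated"
  }
  names(lab) <- clusterCells
  counts <- table(factor(lab, levels = c("associated", "non-associated",
                                         "unassigned")))
  message("subcluster split: ", paste(names(counts), counts, sep = " = ",
                                      collapse = ", "),
          " of ", length(clusterCells), " cells")
  if (counts["associated"] == 0 || counts["non-associated"] == 0)
    stop("empty subcluster; adjust the p-value thresholds")
  lab
}

#' Overlap of up-regulated DEGs with locus annotation and disease set
#'
#' Counts the subcluster's up-regulated DEGs, their intersection with the
#' locus ("TAD") genes and with the disease set, and returns the
#' DEG-approach candidates: up-DEGs inside loci but outside the disease
#' set.
#'
#' @param deg DEG table from [wilcoxonMarkers()] (associated vs
#'   non-associated subcluster).
#' @param tads a [TadAnnotation-class].
#' @param geneSet the disease [WeightedGeneSet-class].
#' @param alpha BH-adjusted p threshold (default 0.05).
#' @param log2fcMin minimum log2 fold change for "up" (default 0).
#' @return list: `n_up`, `n_up_tad`, `n_up_disease`, `candidates`
#'   (data.frame gene, log2fc, padj, locus).
#' @export
overlapWithAnnotation <- function(deg, tads, geneSet, alpha = 0.05,
                                  log2fcMin = 0) {
  up <- deg[deg$padj < alpha & deg$log2fc > log2fcMin, , drop = FALSE]
  tg <- tadGenes(tads)
  inTad <- up$gene %in% tg
  inSet <- up$gene %in% geneIds(geneSet)
  cand <- up[inTad & !inSet, c("gene", "log2fc", "padj"), drop = FALSE]
  cand <- cand[order(cand$padj, cand$gene), , drop = FALSE]
  cand$locus <- unname(tadGeneMap(tads)[cand$gene])
  list(n_up = nrow(up), n_up_tad = sum(inTad), n_up_disease = sum(inSet),
       candidates = cand)
}
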