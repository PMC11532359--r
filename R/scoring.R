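#' Bin genes by mean and variance of normalized expression
#'
#' Quantile bins on the mean of log-normalized expression, then quantile
#' bins on the variance within each mean bin. Matched-control gene sets are
#' drawn within these bins so that control genes share the expression
#' profile of the disease genes. Ties break by gene order
#' (deterministic).
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param nMeanBins,nVarBins bin grid (default 10 x 10).
#' @return data.frame: gene, mean, var, meanBin, varBin, bin (combined id),
#'   restricted to detected genes (total count > 0).
#' @export
computeGeneBins <- function(sce, nMeanBins = 10, nVarBins = 10) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  detected <- Matrix::rowSums(counts) > 0
  x <- SummarizedExperiment::assay(sce, "logcounts")[detected, , drop = FALSE]
  mu <- Matrix::rowMeans(x)
  v <- rowVarsSparse(x, mu)
  ng <- length(mu)
  if (ng < nMeanBins) {
    warning("fewer detected genes than mean bins; reducing bin count")
    nMeanBins <- max(1L, ng)
  }
  meanBin <- quantileBin(mu, nMeanBins)
  varBin <- integer(ng)
  for (b in unique(meanBin)) {
    idx <- which(meanBin == b)
    nv <- min(nVarBins, length(idx))
    varBin[idx] <- quantileBin(v[idx], nv)
  }
  data.frame(gene = rownames(x), mean = mu, var = v,
             meanBin = meanBin, varBin = varBin,
             bin = paste(meanBin, varBin, sep = "."),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Equal-count quantile bins; ties broken by original order. Fewer unique
# values than bins collapse the grid (all-identical values -> one bin).
quantileBin <- function(x, nBins) {
  n <- length(x)
  nBins <- min(nBins, length(unique(x)))
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * nBins / n))
}

#' Draw expression-matched Monte Carlo control gene sets
#'
#' Each control set replaces every disease gene with a uniformly random
#' gene from the same mean x variance bin, sampled without replacement
#' within a control set (with replacement, plus a warning, if a bin is
#' exhausted). Control genes inherit the disease gene's weight, so every
#' control set reproduces the disease set's bin histogram exactly.
#'
#' @param bins output of [computeGeneBins()].
#' @param geneSet a [WeightedGeneSet-class]; every gene must be detected
#'   (present in `bins`).
#' @param B number of control sets (>= 1).
#' @param seed RNG seed.
#' @return list with `genes` (B x set-size character matrix) and `weights`
#'   (weights of the disease genes, shared by all sets).
#' @export
sampleControlSets <- function(bins, geneSet, B = 1000, seed = 0) {
  if (B < 1) stop("at least 1 control set required")
  genes <- geneIds(geneSet)
  miss <- setdiff(genes, bins$gene)
  if (length(miss))
    stop("gene set contains undetected genes (filter first): ",
         paste(head(miss), collapse = ", "))
  set.seed(seed)
  binOf <- setNames(bins$bin, bins$gene)
  setBins <- binOf[genes]
  byBin <- split(bins$gene, bins$bin)
  posByBin <- split(seq_along(genes), setBins)
  ctrl <- matrix(NA_character_, B, length(genes))
  warned <- FALSE
  for (b in names(posByBin)) {
    pos <- posByBin[[b]]
    pool <- byBin[[b]]
    need <- length(pos)
    if (need > length(pool)) {
      if (!warned) {
        warning("bin ", b, " exhausted; sampling with replacement")
        warned <- TRUE
      }
      draws <- matrix(sample(pool, need * B, replace = TRUE), B, need)
    } else {
      draws <- t(replicate(B, sample(pool, need)))
      if (need == 1) draws <- matrix(draws, B, 1)
    }
    ctrl[, pos] <- draws
  }
  list(genes = ctrl, weights = unname(geneWeights(geneSet)))
}

#' Per-cell disease-relevance scores against matched controls
#'
#' The raw score of cell c is the weighted mean of the set genes'
#' log-normalized expression, `S_c = sum(w_g * x_cg) / sum(w_g)`; the same
#' formula is applied to each control set (control genes inherit weights).
#' Normalization is two-step: first every score vector (the observed one
#' and each control set's) is centered across cells, removing set-level
#' offsets (a control set whose genes are systematically hotter than their
#' bin-mates would otherwise shift all cells at once); then the normalized
#' score is `(S_c - mean_b(ctrl_cb)) / sd_b(ctrl_cb)`, with control scores
#' normalized identically using leave-self-out mean and sd. The empirical
#' p-value pools normalized control scores over all cells and sets:
#' `p_c = (1 + #{pooled >= norm_c}) / (1 + B * n_cells)`, and BH FDR is
#' computed across cells.
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param geneSet a [WeightedGeneSet-class] of detected genes.
#' @param controls output of [sampleControlSets()] (B >= 3).
#' @param varianceWeighting additionally scale each gene's weight by the
#'   inverse of its expression standard deviation (off by default).
#' @param bins gene bins (required when `varianceWeighting = TRUE`).
#' @return A [CellScores-class].
#' @export
scoreCells <- function(sce, geneSet, controls, varianceWeighting = FALSE,
                       bins = NULL) {
  x <- SummarizedExperiment::assay(sce, "logcounts")
  genes <- geneIds(geneSet)
  w <- unname(geneWeights(geneSet))
  if (!all(is.finite(w)) || any(w < 0) || all(w == 0))
    stop("weights must be finite, non-negative, and not all zero")
  B <- nrow(controls$genes)
  if (B < 3) stop("at least 3 control sets required for normalization")
  sdOf <- NULL
  if (varianceWeighting) {
    if (is.null(bins)) stop("variance weighting requires 'bins'")
    sdOf <- setNames(sqrt(pmax(bins$var, 0)), bins$gene)
    sdOf[sdOf == 0] <- Inf
  }
  effW <- function(gg) if (is.null(sdOf)) w else w / sdOf[gg]

  wObs <- effW(genes)
  raw <- as.vector(Matrix::crossprod(x[genes, , drop = FALSE], wObs)) /
    sum(wObs)

  # sparse weight matrix: detected genes x B control sets
  rowIdx <- match(as.vector(t(controls$genes)), rownames(x))
  colIdx <- rep(seq_len(B), each = length(genes))
  wCtrl <- if (is.null(sdOf)) rep(w, times = B) else
    rep(w, times = B) / sdOf[as.vector(t(controls$genes))]
  wm <- Matrix::sparseMatrix(i = rowIdx, j = colIdx, x = wCtrl,
                             dims = c(nrow(x), B))
  sumW <- Matrix::colSums(wm)
  ctrlRaw <- as.matrix(Matrix::crossprod(x, wm)) # cells x B
  ctrlRaw <- sweep(ctrlRaw, 2, sumW, `/`)

  # step 1: center each score vector across cells (set-level offsets out)
  rawC <- raw - mean(raw)
  ctrlRaw <- sweep(ctrlRaw, 2, colMeans(ctrlRaw))

  mu <- rowMeans(ctrlRaw)
  s1 <- rowSums(ctrlRaw)
  s2 <- rowSums(ctrlRaw^2)
  sdFull <- sqrt(pmax((s2 - s1^2 / B) / (B - 1), 0))
  degenerate <- sdFull == 0
  if (any(degenerate))
    warning(sum(degenerate), " cell(s) with zero control-score sd; ",
            "normalized score set to 0, p = 1")
  norm <- ifelse(degenerate, 0, (rawC - mu) / sdFull)

  # leave-self-out normalization of the control scores themselves
  muLoo <- (s1 - ctrlRaw) / (B - 1)
  varLoo <- (s2 - ctrlRaw^2 - (s1 - ctrlRaw)^2 / (B - 1)) / (B - 2)
  sdLoo <- sqrt(pmax(varLoo, 0))
  ctrlNorm <- (ctrlRaw - muLoo) / sdLoo
  ctrlNorm[!is.finite(ctrlNorm)] <- 0

  pooled <- sort(as.vector(ctrlNorm))
  nPool <- length(pooled)
  nGe <- nPool - findInterval(norm, pooled, left.open = TRUE)
  pval <- (1 + nGe) / (1 + nPool)
  pval[degenerate] <- 1
  new("CellScores", cells = colnames(x), raw = raw, normalized = norm,
      pval = pval, fdr = p.adjust(pval, "BH"), controls = ctrlNorm)
}
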