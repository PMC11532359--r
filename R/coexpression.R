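#' Build metacells by k-nearest-neighbor aggregation
#'
#' Within one cell group, each cell's candidate metacell is itself plus its
#' k - 1 nearest neighbors in the embedding. Candidates are visited in
#' seeded random order and accepted while their pairwise shared-cell count
#' with every accepted metacell stays at or below `maxShared`, until
#' `targetN` metacells are accepted or the candidates are exhausted.
#' Member counts are summed and log1p depth-normalized.
#'
#' @param sce `SingleCellExperiment` with counts and a `"PCA"` reducedDim.
#' @param group cell group to aggregate (matched against `labels`).
#' @param labels group label per cell (named by cell or in column order).
#' @param k cells per metacell (default 25).
#' @param maxShared maximum pairwise shared cells (default 10).
#' @param targetN maximum number of metacells (default 250).
#' @param seed RNG seed for the visiting order.
#' @param scale depth-scaling constant for normalization.
#' @return A [Metacells-class].
#' @export
buildMetacells <- function(sce, group, labels, k = 25, maxShared = 10,
                           targetN = 250, seed = 0, scale = 1e4) {
  if (!is.null(names(labels))) labels <- labels[colnames(sce)]
  cells <- which(as.character(labels) == as.character(group))
  if (length(cells) < k)
    stop("group '", group, "' has fewer than k = ", k, " cells")
  emb <- SingleCellExperiment::reducedDim(sce, "PCA")[cells, , drop = FALSE]
  nn <- knnIndex(emb, k - 1)
  candidates <- cbind(seq_along(cells), nn)
  set.seed(seed)
  order_ <- sample(nrow(candidates))
  accepted <- list()
  memberCount <- integer(length(cells))
  for (ci in order_) {
    cand <- candidates[ci, ]
    ok <- TRUE
    for (a in accepted) {
      if (sum(cand %in% a) > maxShared) { ok <- FALSE; break }
    }
    if (ok) {
      accepted[[length(accepted) + 1L]] <- cand
      if (length(accepted) >= targetN) break
    }
  }
  counts <- SummarizedExperiment::assay(sce, "counts")[, cells, drop = FALSE]
  agg <- vapply(accepted, function(m)
    Matrix::rowSums(counts[, m, drop = FALSE]), numeric(nrow(counts)))
  tot <- colSums(agg)
  expr <- log1p(sweep(agg, 2, tot / scale, `/`))
  colnames(expr) <- sprintf("mc%04d", seq_along(accepted))
  new("Metacells", expr = expr, members = accepted,
      cells = colnames(sce)[cells], group = as.character(group),
      k = as.integer(k))
}

signedAdjacency <- function(cr, beta) ((1 + cr) / 2)^beta

#' Choose the soft power for a signed co-expression network
#'
#' For each candidate power, the signed adjacency
#' `a_ij = ((1 + cor_ij) / 2)^beta` is formed, connectivities
#' `k_i = sum_{j != i} a_ij` are binned (10 equal-width bins), and the
#' scale-free fit is the sign-corrected R^2 of `log10 p(k)` on
#' `log10 mean(k)`. The chosen power is the smallest one reaching
#' `r2Threshold`, else `fallback` with a warning.
#'
#' @param metacells a [Metacells-class] (or genes x metacells matrix).
#' @param powers candidate powers (default 1:20).
#' @param r2Threshold scale-free fit threshold (default 0.8).
#' @param fallback power used when no candidate fits (default 9).
#' @param nBreaks connectivity bins for the fit.
#' @return list: `scan` (data.frame power, r2, mean_k), `power`, `cor`
#'   (the gene correlation matrix, reused by module detection), `genes`.
#' @export
selectSoftPower <- function(metacells, powers = 1:20, r2Threshold = 0.8,
                            fallback = 9, nBreaks = 10) {
  expr <- if (methods::is(metacells, "Metacells")) metacellExpr(metacells)
          else metacells
  if (ncol(expr) < 30)
    warning("fewer than 30 metacells; correlations will be noisy")
  v <- apply(expr, 1, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant gene(s) dropped before correlation")
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) < 10) stop("too few variable genes for a network scan")
  cr <- cor(t(expr))
  scan <- lapply(powers, function(b) {
    a <- signedAdjacency(cr, b)
    ki <- rowSums(a) - 1
    data.frame(power = b, r2 = scaleFreeR2(ki, nBreaks),
               mean_k = mean(ki))
  })
  scan <- do.call(rbind, scan)
  hit <- which(scan$r2 >= r2Threshold)
  power <- if (length(hit)) scan$power[hit[1]] else {
    warning("no power reached R^2 >= ", r2Threshold, "; using ", fallback)
    fallback
  }
  list(scan = scan, power = power, cor = cr, genes = rownames(expr))
}

# Sign-corrected scale-free topology fit index.
scaleFreeR2 <- function(k, nBreaks = 10) {
  brk <- seq(min(k), max(k), length.out = nBreaks + 1)
  bin <- cut(k, brk, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  keep <- !is.na(dk) & dk > 0 & !is.na(pk) & pk > 0
  if (sum(keep) < 3) return(0)
  fit <- lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[2]) * r2
}

#' Topological overlap matrix of a signed adjacency
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal; `k_i` excludes the diagonal.
#'
#' @param adj symmetric adjacency with entries in `[0, 1]`, unit diagonal.
#' @return TOM matrix (symmetric, entries in `[0, 1]`, diagonal 1).
#' @export
tomSimilarity <- function(adj) {
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules from metacell expression
#'
#' Builds the signed adjacency at the chosen power, its topological
#' overlap matrix, average-linkage hierarchical clustering on `1 - TOM`, a
#' static tree cut at `cutHeight`, removal of branches below
#' `minModuleSize` (label 0 = unassigned), iterative merging of modules
#' whose eigengenes correlate above `1 - mergeCut`, and kME pruning:
#' genes whose correlation with their own module eigengene falls below
#' `minKME` are released to unassigned (loose average-linkage branches
#' otherwise absorb uncorrelated genes). Final labels are ordered by
#' decreasing module size.
#'
#' @param metacells a [Metacells-class] (or genes x metacells matrix).
#' @param power soft power (e.g. from [selectSoftPower()]).
#' @param minModuleSize smallest retained branch (default 30).
#' @param mergeCut eigengene-correlation merge cut (default 0.2).
#' @param cutHeight static cut height as a fraction of the dendrogram's
#'   maximum merge height (default 0.99; an absolute cut on `1 - TOM`
#'   is brittle because overall tree height shifts with the soft power).
#' @param minKME minimum own-module eigengene correlation to stay
#'   assigned (default 0.3).
#' @param minCoherence minimum mean own-module kME for a module to
#'   survive (default 0.5): a module is a set of substantially
#'   inter-correlated genes, and diffuse clusters held together only by
#'   weak shared (e.g. compositional) variation are dissolved.
#' @return A [ModuleSet-class] (eigengenes, kME and hub genes filled in).
#' @export
detectModules <- function(metacells, power, minModuleSize = 30,
                          mergeCut = 0.2, cutHeight = 0.99, minKME = 0.3,
                          minCoherence = 0.5) {
  expr <- if (methods::is(metacells, "Metacells")) metacellExpr(metacells)
          else metacells
  v <- apply(expr, 1, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant gene(s) left unassigned")
  }
  use <- which(v > 0)
  cr <- cor(t(expr[use, , drop = FALSE]))
  tom <- tomSimilarity(signedAdjacency(cr, power))
  h <- hclust(as.dist(1 - tom), method = "average")
  branch <- cutree(h, h = cutHeight * max(h$height))
  sizes <- table(branch)
  keep <- as.integer(names(sizes)[sizes >= minModuleSize])
  labels <- integer(nrow(expr))
  nextLab <- 1L
  for (b in keep) {
    labels[use[branch == b]] <- nextLab
    nextLab <- nextLab + 1L
  }
  if (all(labels == 0L))
    warning("no module reached the minimum size; all genes unassigned")
  ms <- new("ModuleSet", genes = rownames(expr), labels = labels,
            eigengenes = matrix(0, ncol(expr), 0),
            kme = matrix(0, nrow(expr), 0), hubGenes = list(),
            power = as.numeric(power))
  ms <- computeEigengenes(expr, ms)
  ms <- mergeModules(expr, ms, mergeCut)
  ms <- pruneByKME(expr, ms, minKME, minModuleSize)
  ms <- dropIncoherent(expr, ms, minCoherence)
  relabelBySize(expr, ms)
}

# Dissolve modules whose mean own-module kME is below the coherence floor.
dropIncoherent <- function(expr, ms, minCoherence) {
  labs <- sort(unique(ms@labels[ms@labels > 0L]))
  if (!length(labs)) return(ms)
  for (l in labs) {
    genes <- ms@labels == l
    meanKme <- mean(ms@kme[genes, as.character(l)])
    if (meanKme < minCoherence) ms@labels[genes] <- 0L
  }
  computeEigengenes(expr, ms)
}

# Release genes whose own-module kME falls below the threshold; dissolve
# modules dropping under the minimum size.
pruneByKME <- function(expr, ms, minKME, minModuleSize) {
  if (!ncol(ms@kme)) return(ms)
  own <- rep(NA_real_, length(ms@labels))
  assigned <- ms@labels > 0L
  own[assigned] <- ms@kme[cbind(which(assigned),
                                match(ms@labels[assigned],
                                      as.integer(colnames(ms@kme))))]
  drop <- assigned & own < minKME
  if (any(drop)) ms@labels[drop] <- 0L
  sizes <- table(ms@labels[ms@labels > 0L])
  small <- as.integer(names(sizes)[sizes < minModuleSize])
  if (length(small)) ms@labels[ms@labels %in% small] <- 0L
  computeEigengenes(expr, ms)
}

# Eigengene = first principal component of the module's standardized
# gene x metacell submatrix, sign-aligned with the module mean profile.
computeEigengenes <- function(expr, ms) {
  labs <- sort(unique(ms@labels[ms@labels > 0L]))
  if (!length(labs)) {
    ms@eigengenes <- matrix(0, ncol(expr), 0)
    ms@kme <- matrix(0, nrow(expr), 0)
    ms@hubGenes <- list()
    return(ms)
  }
  eg <- vapply(labs, function(l) {
    sub <- expr[ms@labels == l, , drop = FALSE]
    subs <- t(scale(t(sub)))
    subs[!is.finite(subs)] <- 0
    sv <- svd(subs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (cor(e, colMeans(subs)) < 0) e <- -e
    e
  }, numeric(ncol(expr)))
  colnames(eg) <- as.character(labs)
  rownames(eg) <- colnames(expr)
  kme <- cor(t(as.matrix(expr)), eg)
  kme[!is.finite(kme)] <- 0
  rownames(kme) <- rownames(expr)
  ms@eigengenes <- eg
  ms@kme <- kme
  ms@hubGenes <- setNames(lapply(labs, function(l) {
    genes <- ms@genes[ms@labels == l]
    k <- kme[genes, as.character(l)]
    genes[order(-k, genes)][seq_len(min(10, length(genes)))]
  }), as.character(labs))
  ms
}

mergeModules <- function(expr, ms, mergeCut) {
  repeat {
    labs <- colnames(ms@eigengenes)
    if (length(labs) < 2) return(ms)
    cc <- cor(ms@eigengenes)
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] <= 1 - mergeCut) return(ms)
    from <- as.integer(labs[mx[2]]); into <- as.integer(labs[mx[1]])
    ms@labels[ms@labels == from] <- into
    ms <- computeEigengenes(expr, ms)
  }
}

relabelBySize <- function(expr, ms) {
  labs <- ms@labels
  if (!any(labs > 0L)) return(ms)
  sz <- sort(table(labs[labs > 0L]), decreasing = TRUE)
  map <- setNames(seq_along(sz), names(sz))
  newLabs <- ifelse(labs > 0L, map[as.character(labs)], 0L)
  ms@labels <- as.integer(newLabs)
  computeEigengenes(expr, ms)
}

#' Rank modules by their fraction of locus ("TAD") genes
#'
#' `percentage = |module ∩ TAD genes| / |module| * 100`; the top `topN`
#' modules are selected, ties broken by larger absolute TAD-gene count,
#' then label order.
#'
#' @param ms a [ModuleSet-class].
#' @param tads a [TadAnnotation-class].
#' @param topN modules to select (default 3).
#' @return data.frame (all modules): module, size, n_tad, pct_tad,
#'   selected.
#' @export
rankModulesByTadFraction <- function(ms, tads, topN = 3) {
  mods <- moduleGenes(ms)
  if (length(mods) < topN)
    warning("fewer modules than topN; selecting all")
  tg <- tadGenes(tads)
  tab <- data.frame(module = as.integer(names(mods)),
                    size = lengths(mods),
                    n_tad = vapply(mods, function(g) sum(g %in% tg),
                                   integer(1)))
  tab$pct_tad <- tab$n_tad / tab$size * 100
  ord <- order(-tab$pct_tad, -tab$n_tad, tab$module)
  tab <- tab[ord, , drop = FALSE]
  tab$selected <- seq_len(nrow(tab)) <= topN
  rownames(tab) <- NULL
  tab
}

#' Pairwise gene overlap between two module assignments
#'
#' @param msA,msB [ModuleSet-class] objects (e.g. from two cell types).
#' @param modulesA,modulesB module labels to compare (default all).
#' @return data.frame: module_a, module_b, overlap.
#' @export
moduleOverlap <- function(msA, msB, modulesA = NULL, modulesB = NULL) {
  ga <- moduleGenes(msA); gb <- moduleGenes(msB)
  if (!is.null(modulesA)) ga <- ga[as.character(modulesA)]
  if (!is.null(modulesB)) gb <- gb[as.character(modulesB)]
  out <- expand.grid(module_a = names(ga), module_b = names(gb),
                     stringsAsFactors = FALSE)
  out$overlap <- mapply(function(a, b) length(intersect(ga[[a]], gb[[b]])),
                        out$module_a, out$module_b)
  out
}
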