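test_that("log1p depth normalization matches the closed form", {
  sce <- makeSce(matrix(c(1, 1, 2), nrow = 3))
  sce <- normalizeLog1p(sce)
  x <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  expect_equal(x[1, 1], log(1 + 1 / 4 * 1e4), tolerance = 1e-10)
  expect_equal(x[1, 1], 7.8244, tolerance = 1e-4)
  # zero counts stay zero
  sce2 <- normalizeLog1p(makeSce(matrix(c(0, 3), nrow = 2)))
  expect_equal(as.matrix(SummarizedExperiment::assay(sce2,
                                                     "logcounts"))[1, 1], 0)
})

test_that("normalization is invariant to per-cell depth scaling", {
  counts <- matrix(rpois(60, 4), 6, 10)
  doubled <- counts
  doubled[, 3] <- counts[, 3] * 2
  a <- normalizeLog1p(makeSce(counts))
  b <- normalizeLog1p(makeSce(doubled))
  expect_equal(as.matrix(SummarizedExperiment::assay(a, "logcounts"))[, 3],
               as.matrix(SummarizedExperiment::assay(b, "logcounts"))[, 3])
})

test_that("all-zero cells stay all-zero with a warning", {
  counts <- matrix(1, 4, 3)
  counts[, 2] <- 0
  expect_warning(sce <- normalizeLog1p(makeSce(counts)), "zero total")
  expect_true(all(as.matrix(
    SummarizedExperiment::assay(sce, "logcounts"))[, 2] == 0))
})

test_that("HVG selection ranks variable genes above constant ones", {
  set.seed(1)
  counts <- matrix(5, 40, 60)          # constant block
  counts[1:10, ] <- matrix(rnbinom(600, mu = 5, size = 0.3), 10)
  sce <- normalizeLog1p(makeSce(counts))
  hv <- selectHVGs(sce, n = 10)
  expect_setequal(hv, sprintf("g%03d", 1:10))
  # n beyond the expressed-gene count warns and returns all expressed
  expect_warning(all40 <- selectHVGs(sce, n = 45), "expressed")
  expect_lte(length(all40), 40)
})

test_that("planted module genes are enriched among HVGs", {
  ors <- vapply(1:5, function(s) {
    cfg <- simConfig(nGenes = 300, nCells = 500, cellTypes = c(all = 1),
                     nMarkersPerType = 0, nSubpopMarkers = 0,
                     diseaseSetSize = 0, diseaseFold = 1,
                     affected = data.frame(cell_type = "all", fraction = 0),
                     nLocusGenes = 0, nUndetectedLocusGenes = 0,
                     nCoregBystanders = 0, moduleSizes = c(50L, 50L),
                     moduleActiveType = "all",
                     moduleTadCounts = c(0L, 0L), nOutsideHits = 0,
                     nTads = 2, seed = s)
    sim <- simulateCounts(cfg)
    sce <- normalizeLog1p(sim$sce)
    hv <- selectHVGs(sce, n = 100)
    inMod <- sim$truth$genes$module[match(rownames(sce),
                                          sim$truth$genes$gene)] > 0
    isHv <- rownames(sce) %in% hv
    tab <- table(isHv, inMod)
    (tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"]) /
      (tab["TRUE", "FALSE"] * tab["FALSE", "TRUE"])
  }, numeric(1))
  expect_gt(mean(ors), 2)
})

test_that("PCA captures rank-1 structure and matches a dense eigensolver", {
  set.seed(3)
  u <- rnorm(20); v <- rnorm(50)
  sce <- makeNormalizedSce(abs(outer(u, v)))
  sce <- embedPCA(sce, rownames(sce), nPcs = 3, clip = 100)
  ve <- attr(SingleCellExperiment::reducedDim(sce, "PCA"), "varExplained")
  expect_gt(ve[1] / sum(ve), 0.99)

  sce2 <- makeNormalizedSce(matrix(rnorm(20 * 50, sd = 2), 20, 50))
  sce2 <- embedPCA(sce2, rownames(sce2), nPcs = 10, clip = 100)
  ve2 <- attr(SingleCellExperiment::reducedDim(sce2, "PCA"),
              "varExplained")
  x <- as.matrix(SummarizedExperiment::assay(sce2, "logcounts"))
  xs <- t(scale(t(x)))  # same per-gene standardization
  ev <- eigen(stats::cov(t(xs)), symmetric = TRUE)$values
  expect_equal(ve2, ev[1:10], tolerance = 1e-8)
})

test_that("PCA is equivariant under cell permutation and errors on bad nPcs", {
  sce <- makeNormalizedSce(matrix(rnorm(300), 10, 30))
  a <- embedPCA(sce, rownames(sce), nPcs = 4)
  perm <- sample(ncol(sce))
  b <- embedPCA(sce[, perm], rownames(sce), nPcs = 4)
  ea <- SingleCellExperiment::reducedDim(a, "PCA")
  eb <- SingleCellExperiment::reducedDim(b, "PCA")
  expect_equal(ea[rownames(eb), ], unclass(eb), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(embedPCA(sce, rownames(sce), nPcs = 40), "nPcs")
  expect_error(embedPCA(sce, c("nope", rownames(sce))), "absent")
})

test_that("SNN-Louvain separates well-separated blobs and is deterministic", {
  set.seed(11)
  emb <- rbind(matrix(rnorm(100 * 2, sd = 0.1), ncol = 2),
               matrix(rnorm(100 * 2, mean = 10, sd = 0.1), ncol = 2))
  rownames(emb) <- sprintf("c%03d", 1:200)
  truth <- rep(0:1, each = 100)
  # coarse resolution recovers the two blobs exactly
  lab <- clusterCells(emb, kNeighbors = 20, resolution = 0.5, seed = 1)
  expect_equal(mclust::adjustedRandIndex(lab, truth), 1)
  # at the default resolution clusters may subdivide blobs but never
  # bridge them
  labD <- clusterCells(emb, kNeighbors = 20, seed = 1)
  expect_true(all(rowSums(table(labD, truth) > 0) == 1))
  expect_identical(labD, clusterCells(emb, kNeighbors = 20, seed = 1))
  expect_error(clusterCells(emb, kNeighbors = 300), "kNeighbors")
})

test_that("clustering recovers planted cell types", {
  aris <- vapply(1:3, function(s) {
    cfg <- simConfig(nGenes = 400, nCells = 600,
                     cellTypes = c(a = 0.3, b = 0.25, c = 0.2, d = 0.15,
                                   e = 0.1),
                     nMarkersPerType = 40, nSubpopMarkers = 0,
                     diseaseSetSize = 0, diseaseFold = 1,
                     affected = data.frame(cell_type = "a", fraction = 0),
                     nLocusGenes = 0, nUndetectedLocusGenes = 0,
                     nCoregBystanders = 0, moduleSizes = integer(0),
                     moduleTadCounts = integer(0), nOutsideHits = 0,
                     nTads = 2, seed = s)
    sim <- simulateCounts(cfg)
    sce <- normalizeLog1p(sim$sce)
    sce <- embedPCA(sce, selectHVGs(sce, n = 200), nPcs = 15)
    lab <- clusterCells(sce, seed = s)
    mclust::adjustedRandIndex(lab, sim$truth$cells$cell_type)
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("rank-sum markers: exact enumeration, approximation, and edge cases", {
  # identical groups: p = 1, log2FC = 0
  x <- rbind(c(1, 2, 3, 1, 2, 3), c(5, 6, 7, 5, 6, 7))
  sce <- makeNormalizedSce(x)
  deg <- wilcoxonMarkers(sce, colnames(sce)[1:3], colnames(sce)[4:6])
  expect_true(all(deg$p == 1))
  expect_true(all(deg$log2fc == 0))

  # enumeration oracle: A = (1,2,3), B = (4,5,6) -> two-sided p = 0.1
  sce2 <- makeNormalizedSce(matrix(1:6, nrow = 1))
  deg2 <- wilcoxonMarkers(sce2, colnames(sce2)[1:3], colnames(sce2)[4:6])
  expect_equal(deg2$p, 0.1, tolerance = 1e-12)

  # exact path equals stats::pwilcox enumeration on tie-free data
  set.seed(8)
  for (i in 1:20) {
    a <- runif(5); b <- runif(6)
    sceI <- makeNormalizedSce(matrix(c(a, b), nrow = 1))
    mine <- wilcoxonMarkers(sceI, colnames(sceI)[1:5],
                            colnames(sceI)[6:11])$p
    oracle <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(mine, oracle, tolerance = 1e-12)
  }

  # normal approximation matches wilcox.test with tie correction
  set.seed(9)
  m <- matrix(rpois(40 * 30, 2), nrow = 40)
  sceL <- makeNormalizedSce(m)
  degL <- wilcoxonMarkers(sceL, colnames(sceL)[1:15], colnames(sceL)[16:30])
  for (g in c(1, 7, 23)) {
    wt <- suppressWarnings(
      stats::wilcox.test(m[g, 1:15], m[g, 16:30], exact = FALSE,
                         correct = TRUE))$p.value
    expect_equal(degL$p[g], wt, tolerance = 1e-10)
  }

  expect_error(wilcoxonMarkers(sceL, character(0), colnames(sceL)[1:5]),
               "non-empty")
})

test_that("BH adjustment equals the hand step-up formula and is idempotent", {
  set.seed(4)
  for (i in 1:5) {
    p <- runif(50)^2
    hand <- {
      n <- length(p); o <- order(p, decreasing = TRUE)
      ro <- order(o)
      pmin(1, cummin(n / (n:1) * p[o]))[ro]
    }
    expect_equal(p.adjust(p, "BH"), hand, tolerance = 1e-14)
    perm <- sample(50)
    expect_equal(p.adjust(p[perm], "BH"), hand[perm], tolerance = 1e-14)
  }
})
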