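test_that("Geary's C matches hand and brute-force computations", {
  # 4-node path, x = (0,0,1,1): C = 0.5 by hand
  edges <- cbind(c(1, 2, 3), c(2, 3, 4))
  expect_equal(gearyC(c(0, 0, 1, 1), edges), 0.5, tolerance = 1e-12)
  # brute-force double sum on random graphs
  set.seed(2)
  for (i in 1:5) {
    n <- 12
    a <- matrix(0, n, n)
    idx <- which(upper.tri(a))
    on <- sample(idx, 25)
    a[on] <- runif(25)
    a <- a + t(a)
    x <- rnorm(n)
    num <- 0; W <- 0
    for (p in 1:n) for (q in 1:n) {
      num <- num + a[p, q] * (x[p] - x[q])^2
      W <- W + a[p, q]
    }
    brute <- (n - 1) * num / (2 * W * sum((x - mean(x))^2))
    eu <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
    mine <- gearyC(x, eu, w = a[eu])
    expect_equal(mine, brute, tolerance = 1e-12)
  }
  # constant vector: undefined
  expect_true(is.na(gearyC(rep(1, 4), edges)))
})

test_that("group association follows the Monte Carlo formula and flags tiny groups", {
  # B = 1, control mean below observed -> p = 1/2
  sc <- makeScores(normalized = rep(1, 30),
                   controls = matrix(0, 30, 1))
  expect_warning(res <- groupAssociation(sc, rep("g", 30), minCells = 50),
                 "unreliable")
  expect_equal(res$p, 0.5)
  expect_false(res$reliable)
  # exact count formula
  ctrl <- matrix(rep(c(2, 0.5, -1, 3), each = 25), 25, 4)
  sc2 <- makeScores(normalized = rep(1, 25), controls = ctrl)
  res2 <- groupAssociation(sc2, rep("g", 25))
  expect_equal(res2$p, (1 + 2) / (1 + 4))  # controls 2 and 3 beat stat 1
})

test_that("group association is invariant to cell order and label names", {
  set.seed(3)
  sc <- makeScores(rnorm(60), matrix(rnorm(60 * 20), 60, 20))
  labels <- rep(c("x", "y", "z"), 20)
  a <- groupAssociation(sc, labels)
  relabeled <- unname(c(x = "B", y = "C", z = "A")[labels])
  b <- groupAssociation(sc, relabeled)
  expect_equal(a$p, b$p[match(relabeled[match(c("x", "y", "z"), labels)],
                              b$group)])
  named <- setNames(labels, sc@cells)
  perm <- sample(60)
  c2 <- groupAssociation(sc, named[perm])
  expect_equal(a$p, c2$p)
})

test_that("heterogeneity testing contrasts structured and constant scores", {
  set.seed(5)
  n <- 80
  emb <- cbind(c(rnorm(20, 5, 0.2), rnorm(60, 0, 0.2)), rnorm(n, 0, 0.2))
  rownames(emb) <- sprintf("c%03d", 1:n)
  # scores elevated exactly on the spatially tight first 20 cells
  norm <- c(rnorm(20, 3, 0.3), rnorm(60, 0, 0.3))
  ctrl <- matrix(rnorm(n * 50), n, 50)
  sc <- makeScores(norm, ctrl)
  het <- groupHeterogeneity(sc, emb, rep("g", n), kNeighbors = 10)
  expect_lt(het$p, 0.05)
  expect_gt(het$one_minus_C, 0)
  # constant scores: undefined statistic, never significant
  scc <- makeScores(rep(2, n), ctrl)
  expect_warning(hc <- groupHeterogeneity(scc, emb, rep("g", n),
                                          kNeighbors = 10),
                 "zero score variance")
  expect_equal(hc$p, 1)
  # groups at or below kNeighbors cells return NA
  hs <- groupHeterogeneity(sc, emb, rep(c("g", "tiny"), c(70, 10)),
                           kNeighbors = 15)
  expect_true(is.na(hs$p[hs$group == "tiny"]))
})

test_that("score-gene correlation matches the textbook formula", {
  set.seed(6)
  x <- matrix(abs(rnorm(5 * 5)), 5, 5)
  sce <- makeNormalizedSce(x)
  norm <- rnorm(5)
  sc <- makeScores(norm, matrix(rnorm(5 * 10), 5, 10))
  sc@cells <- colnames(sce)
  res <- correlateScoreWithGenes(sce, sc)
  for (g in 1:5)
    expect_equal(res$r[g], cor(x[g, ], norm), tolerance = 1e-12)
  # a gene equal to the score vector correlates perfectly
  x2 <- rbind(norm - min(norm), x)
  sce2 <- makeNormalizedSce(x2)
  sc@cells <- colnames(sce2)
  expect_equal(correlateScoreWithGenes(sce2, sc)$r[1], 1,
               tolerance = 1e-12)
  # constant genes are flagged with r = 0
  x3 <- rbind(rep(1, 5), x)
  sce3 <- makeNormalizedSce(x3)
  sc@cells <- colnames(sce3)
  res3 <- correlateScoreWithGenes(sce3, sc)
  expect_true(res3$constant[1])
  expect_equal(res3$r[1], 0)
})

test_that("depth-correlation QC behaves at its extremes and under the null", {
  counts <- matrix(rpois(50 * 100, 3), 50, 100)
  sce <- makeSce(counts)
  depth <- colSums(counts)
  sc <- makeScores(as.numeric(depth), matrix(0, 100, 3))
  sc@cells <- colnames(sce)
  expect_equal(qcDepthCorrelation(sc, sce)$r, 1, tolerance = 1e-12)
  # constant depth: undefined, reported 0
  sceC <- makeSce(matrix(1, 5, 20))
  scC <- makeScores(rnorm(20), matrix(0, 20, 3))
  scC@cells <- colnames(sceC)
  expect_warning(qc <- qcDepthCorrelation(scC, sceC), "constant")
  expect_false(qc$defined)
  expect_equal(qc$r, 0)
  # shuffled scores have near-zero depth correlation
  set.seed(8)
  rs <- replicate(20, {
    scN <- makeScores(sample(as.numeric(depth)), matrix(0, 100, 3))
    scN@cells <- colnames(sce)
    qcDepthCorrelation(scN, sce)$r
  })
  expect_lt(median(abs(rs)), 2 / sqrt(100) * 2)
})

test_that("score-threshold split partitions the cluster by its p-value bounds", {
  p <- c(0.005, 0.05, 0.2, 0.01, 0.1, 0.5, 0.002)
  sc <- makeScores(rnorm(7), matrix(rnorm(21), 7, 3), pval = p)
  lab <- suppressMessages(splitByScore(sc, sc@cells))
  expect_identical(unname(lab[1]), "associated")     # p = 0.005
  expect_identical(unname(lab[2]), "unassigned")     # p = 0.05
  expect_identical(unname(lab[4]), "associated")     # p = 0.01 inclusive
  expect_identical(unname(lab[5]), "non-associated") # p = 0.1 inclusive
  expect_equal(sum(table(lab)), 7)
  # strict thresholds exclude the boundary cells
  labS <- suppressMessages(splitByScore(sc, sc@cells, inclusive = FALSE))
  expect_identical(unname(labS[4]), "unassigned")
  expect_identical(unname(labS[5]), "unassigned")
  expect_error(splitByScore(sc, sc@cells, pLow = 0.2, pHigh = 0.1),
               "below")
  # empty associated side errors with guidance
  scAllHigh <- makeScores(rnorm(4), matrix(rnorm(12), 4, 3),
                          pval = rep(0.5, 4))
  expect_error(suppressMessages(splitByScore(scAllHigh, scAllHigh@cells)),
               "threshold")
})

test_that("DEG overlap arithmetic reproduces the counting rule", {
  # 40 up-DEGs of which 31 TAD genes, 25 of those in the disease set
  genes <- sprintf("d%02d", 1:40)
  deg <- data.frame(gene = c(genes, "downA"),
                    log2fc = c(rep(1, 40), -2),
                    p = rep(1e-4, 41), padj = rep(1e-3, 41),
                    meanA = 1, meanB = 0.5,
                    up = c(rep(TRUE, 40), FALSE))
  tadGenesV <- genes[1:31]
  geneMap <- setNames(rep("L1", 31), tadGenesV)
  tads <- makeTads(geneMap)
  set <- WeightedGeneSet(genes[1:25])
  ov <- overlapWithAnnotation(deg, tads, set)
  expect_equal(ov$n_up, 40)
  expect_equal(ov$n_up_tad, 31)
  expect_equal(ov$n_up_disease, 25)
  expect_equal(nrow(ov$candidates), 6)
  expect_setequal(ov$candidates$gene, genes[26:31])
  # disease set covering all TAD genes leaves no candidates
  ov2 <- overlapWithAnnotation(deg, tads, WeightedGeneSet(tadGenesV))
  expect_equal(nrow(ov2$candidates), 0)
})
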