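# Small embedded SCE for metacell tests: one group with latent structure.
metacellFixture <- function(seed = 1, nGenes = 120, nCells = 300) {
  cfg <- simConfig(nGenes = nGenes, nCells = nCells, cellTypes = c(all = 1),
                   nMarkersPerType = 0, nSubpopMarkers = 0,
                   diseaseSetSize = 0, diseaseFold = 1,
                   affected = data.frame(cell_type = "all", fraction = 0),
                   nLocusGenes = 0, nUndetectedLocusGenes = 0,
                   nCoregBystanders = 0, moduleSizes = c(30L, 30L),
                   moduleActiveType = "all", moduleTadCounts = c(0L, 0L),
                   nOutsideHits = 0, nTads = 2, seed = seed)
  sim <- simulateCounts(cfg)
  sce <- normalizeLog1p(sim$sce)
  sce <- embedPCA(sce, selectHVGs(sce, n = 100), nPcs = 10)
  list(sce = sce, truth = sim$truth)
}

test_that("metacells aggregate exactly k group cells under the overlap cap", {
  fx <- metacellFixture()
  labels <- fx$truth$cells$cell_type
  mc <- buildMetacells(fx$sce, "all", labels, k = 10, maxShared = 3,
                       targetN = 40, seed = 1)
  expect_true(all(lengths(mc@members) == 10))
  expect_lte(ncol(metacellExpr(mc)), 40)
  mem <- mc@members
  for (i in seq_along(mem)) for (j in seq_len(i - 1))
    expect_lte(length(intersect(mem[[i]], mem[[j]])), 3)
  expect_error(buildMetacells(fx$sce, "all", labels, k = 1000), "fewer")
})

test_that("maxShared = k accepts every candidate; maxShared = 0 is a packing", {
  fx <- metacellFixture(2, nGenes = 60, nCells = 100)
  labels <- fx$truth$cells$cell_type
  mcAll <- buildMetacells(fx$sce, "all", labels, k = 25, maxShared = 25,
                          targetN = 60, seed = 1)
  expect_equal(ncol(metacellExpr(mcAll)), 60)
  mc0 <- buildMetacells(fx$sce, "all", labels, k = 25, maxShared = 0,
                        targetN = 250, seed = 1)
  expect_lte(ncol(metacellExpr(mc0)), 4)  # pigeonhole: 100 / 25
})

test_that("metacell aggregation denoises planted gene-gene correlations", {
  gains <- vapply(1:3, function(s) {
    fx <- metacellFixture(seed = s, nGenes = 150, nCells = 500)
    x <- as.matrix(SummarizedExperiment::assay(fx$sce, "logcounts"))
    tm <- setNames(fx$truth$genes$module, fx$truth$genes$gene)
    m1 <- names(tm)[tm == 1]
    scCor <- cor(t(x[m1, ]))
    mc <- buildMetacells(fx$sce, "all", fx$truth$cells$cell_type, k = 25,
                         targetN = 150, seed = s)
    mcCor <- cor(t(metacellExpr(mc)[m1, ]))
    mean(mcCor[upper.tri(mcCor)]) - mean(scCor[upper.tri(scCor)])
  }, numeric(1))
  expect_gte(mean(gains), 0.1)
})

test_that("TOM matches its formula exactly", {
  # 2-gene system: TOM12 = a
  for (a in c(0.1, 0.5, 0.9)) {
    adj <- matrix(c(1, a, a, 1), 2)
    expect_equal(tomSimilarity(adj)[1, 2], a, tolerance = 1e-12)
  }
  # direct triple-loop oracle on random small adjacencies
  set.seed(4)
  for (i in 1:5) {
    g <- 8
    cr <- cor(matrix(rnorm(40 * g), ncol = g))
    adj <- ((1 + cr) / 2)^4
    tom <- tomSimilarity(adj)
    a <- adj; diag(a) <- 0
    k <- rowSums(a)
    for (p in 1:g) for (q in 1:g) {
      if (p == q) next
      l <- sum(a[p, ] * a[, q])
      expected <- (l + a[p, q]) / (min(k[p], k[q]) + 1 - a[p, q])
      expect_equal(tom[p, q], expected, tolerance = 1e-10)
    }
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_true(all(diag(tom) == 1))
  }
})

test_that("soft-power scan: monotone connectivity, threshold choice, refusals", {
  fx <- metacellFixture(3, nGenes = 150, nCells = 500)
  mc <- buildMetacells(fx$sce, "all", fx$truth$cells$cell_type,
                       targetN = 150, seed = 3)
  sp <- selectSoftPower(mc)
  k2 <- sp$scan$mean_k[sp$scan$power == 2]
  k6 <- sp$scan$mean_k[sp$scan$power == 6]
  k12 <- sp$scan$mean_k[sp$scan$power == 12]
  expect_true(k2 >= k6 && k6 >= k12)
  expect_gte(sp$scan$r2[sp$scan$power == sp$power], 0.8)
  expect_error(selectSoftPower(matrix(rnorm(60), 2, 30)), "too few")
})

test_that("adjacency decreases strictly with the power off the diagonal", {
  set.seed(5)
  cr <- cor(matrix(rnorm(200), 20, 10))
  a4 <- ((1 + cr) / 2)^4
  a6 <- ((1 + cr) / 2)^6
  off <- upper.tri(cr) & abs(cr) < 1
  expect_true(all(a6[off] < a4[off]))
})

test_that("planted modules are detected with matching eigengenes and kME", {
  fx <- metacellFixture(7, nGenes = 160, nCells = 600)
  mc <- buildMetacells(fx$sce, "all", fx$truth$cells$cell_type, k = 20,
                       targetN = 200, seed = 7)
  sp <- selectSoftPower(mc)
  ms <- detectModules(metacellExpr(mc)[sp$genes, , drop = FALSE],
                      sp$power, minModuleSize = 20)
  tm <- setNames(fx$truth$genes$module, fx$truth$genes$gene)
  lab <- moduleLabels(ms)
  expect_gte(mclust::adjustedRandIndex(lab, tm[names(lab)]), 0.6)
  # eigengenes are unit norm; own-module kME of hub genes is high
  eg <- moduleEigengenes(ms)
  expect_equal(unname(colSums(eg^2)), rep(1, ncol(eg)), tolerance = 1e-8)
  for (m in colnames(eg)) {
    hubs <- hubGenes(ms)[[m]]
    expect_gte(min(moduleKME(ms)[hubs, m]), 0.5)
  }
})

test_that("degenerate modules: identical genes, one-gene module, null kME", {
  set.seed(9)
  base <- rnorm(50)
  expr <- rbind(matrix(rep(base, 5), 5, byrow = TRUE),
                matrix(rnorm(50 * 5), 5))
  rownames(expr) <- sprintf("g%02d", 1:10)
  colnames(expr) <- sprintf("m%02d", 1:50)
  ms <- new("ModuleSet", genes = rownames(expr),
            labels = c(rep(1L, 5), rep(0L, 5)),
            eigengenes = matrix(0, 50, 0), kme = matrix(0, 10, 0),
            hubGenes = list(), power = 2)
  ms <- scRiskNet:::computeEigengenes(expr, ms)
  expect_equal(unname(moduleKME(ms)[1:5, "1"]), rep(1, 5),
               tolerance = 1e-8)
  # uncorrelated genes have near-zero kME (null bound at 250 metacells)
  expr2 <- rbind(matrix(rep(rnorm(250), 5), 5, byrow = TRUE) +
                   matrix(rnorm(5 * 250, sd = 0.1), 5),
                 matrix(rnorm(20 * 250), 20))
  rownames(expr2) <- sprintf("h%02d", 1:25)
  colnames(expr2) <- sprintf("m%03d", 1:250)
  ms2 <- new("ModuleSet", genes = rownames(expr2),
             labels = c(rep(1L, 5), rep(0L, 20)),
             eigengenes = matrix(0, 250, 0), kme = matrix(0, 25, 0),
             hubGenes = list(), power = 2)
  ms2 <- scRiskNet:::computeEigengenes(expr2, ms2)
  expect_lt(max(abs(moduleKME(ms2)[6:25, "1"])), 0.2)
  # one-gene module: eigengene equals the standardized profile
  ms1 <- new("ModuleSet", genes = rownames(expr2),
             labels = c(1L, rep(0L, 24)),
             eigengenes = matrix(0, 250, 0), kme = matrix(0, 25, 0),
             hubGenes = list(), power = 2)
  ms1 <- scRiskNet:::computeEigengenes(expr2, ms1)
  expect_equal(abs(cor(moduleEigengenes(ms1)[, "1"], expr2[1, ])), 1,
               tolerance = 1e-8)
})

test_that("eigengene explains at least as much module variance as any gene", {
  fx <- metacellFixture(11, nGenes = 100, nCells = 300)
  mc <- buildMetacells(fx$sce, "all", fx$truth$cells$cell_type,
                       targetN = 100, seed = 11)
  ms <- detectModules(mc, 6, minModuleSize = 15)
  expr <- metacellExpr(mc)
  for (m in names(moduleGenes(ms))) {
    genes <- moduleGenes(ms)[[m]]
    sub <- t(scale(t(expr[genes, ])))
    eg <- moduleEigengenes(ms)[, m]
    varBy <- function(v) sum(cor(t(sub), v)^2, na.rm = TRUE)
    best <- max(apply(sub, 1, varBy))
    expect_gte(varBy(eg) + 1e-8, best)
  }
})

test_that("TAD-fraction ranking follows the percentage arithmetic", {
  genes <- sprintf("g%04d", 1:800)
  labels <- integer(800)
  labels[1:348] <- 1L          # 348-gene module with 12 TAD genes
  labels[349:448] <- 2L        # 100-gene module with 30 TAD genes
  labels[449:548] <- 3L        # 100 genes, 0 TAD genes
  ms <- new("ModuleSet", genes = genes, labels = labels,
            eigengenes = matrix(0, 10, 3,
                                dimnames = list(NULL, c("1", "2", "3"))),
            kme = matrix(0, 800, 3), hubGenes = list(), power = 1)
  tadMap <- setNames(rep("L1", 42), c(genes[1:12], genes[349:378]))
  rank <- rankModulesByTadFraction(ms, makeTads(tadMap), topN = 2)
  expect_equal(rank$pct_tad[rank$module == 1], 12 / 348 * 100,
               tolerance = 1e-9)
  expect_equal(round(rank$pct_tad[rank$module == 1], 2), 3.45)
  expect_identical(rank$module[1], 2L)   # 30% beats 3.45%
  expect_true(rank$selected[rank$module == 2])
  expect_false(rank$selected[rank$module == 3])
  # zero-TAD module never outranks a module with TAD genes
  expect_gt(which(rank$module == 3), which(rank$module == 1))
})

test_that("module overlap equals brute-force set intersection", {
  mkMs <- function(genes, labels) {
    new("ModuleSet", genes = genes, labels = as.integer(labels),
        eigengenes = matrix(0, 5, 0), kme = matrix(0, length(genes), 0),
        hubGenes = list(), power = 1)
  }
  a <- mkMs(sprintf("g%02d", 1:30), rep(c(1, 2, 0), each = 10))
  b <- mkMs(sprintf("g%02d", 11:40), rep(c(1, 2, 0), each = 10))
  ov <- moduleOverlap(a, b)
  get <- function(ma, mb) ov$overlap[ov$module_a == ma & ov$module_b == mb]
  expect_equal(get("1", "1"), 0)            # g01-10 vs g11-20
  expect_equal(get("2", "1"), 10)           # g11-20 vs g11-20
  expect_equal(get("2", "2"), 0)
  # identical assignments overlap fully
  ov2 <- moduleOverlap(a, a)
  expect_equal(ov2$overlap[ov2$module_a == "1" & ov2$module_b == "1"], 10)
})

test_that("gene and metacell permutations do not change module structure", {
  fx <- metacellFixture(13, nGenes = 100, nCells = 300)
  mc <- buildMetacells(fx$sce, "all", fx$truth$cells$cell_type,
                       targetN = 120, seed = 13)
  expr <- metacellExpr(mc)
  ms <- detectModules(expr, 6, minModuleSize = 15)
  permMc <- sample(ncol(expr))
  msP <- detectModules(expr[, permMc], 6, minModuleSize = 15)
  expect_identical(moduleLabels(ms), moduleLabels(msP))
  permG <- sample(nrow(expr))
  msG <- detectModules(expr[permG, ], 6, minModuleSize = 15)
  szA <- sort(table(moduleLabels(ms)[moduleLabels(ms) > 0]))
  szB <- sort(table(moduleLabels(msG)[moduleLabels(msG) > 0]))
  expect_equal(unname(szA), unname(szB), ignore_attr = TRUE)
})
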