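#' Competitive gene-set association against gene-level z-scores
#'
#' Ordinary least squares of the gene-based z-score on a module-membership
#' indicator (plus optional covariates) over a background gene universe;
#' the one-sided p-value tests a positive membership coefficient against
#' the t distribution on the residual degrees of freedom. With no
#' covariates this reduces to a two-sample t-test of member vs non-member
#' z-scores. Gene-gene correlation is not modeled; the test assumes
#' approximately independent gene-level statistics.
#'
#' @param gwas data.frame with `gene` and `z` (see [readGwas()]).
#' @param moduleGenes character vector, the tested set (subset of
#'   `background`).
#' @param background character vector of background genes (>= 50).
#' @param covariates optional character vector of `gwas` column names to
#'   adjust for (e.g. `"log_length"`).
#' @return data.frame: coefficient, se, t, p, n_set, n_background.
#' @export
competitiveGeneSetTest <- function(gwas, moduleGenes, background,
                                   covariates = NULL) {
  background <- intersect(background, gwas$gene)
  if (length(background) < 50) stop("background must hold >= 50 genes")
  moduleGenes <- intersect(moduleGenes, background)
  if (length(moduleGenes) == 0) stop("no module gene in the background")
  if (length(moduleGenes) == length(background))
    stop("module equals background: no competitive contrast")
  d <- gwas[match(background, gwas$gene), , drop = FALSE]
  d$member <- as.integer(d$gene %in% moduleGenes)
  form <- if (length(covariates))
    stats::reformulate(c("member", covariates), response = "z")
  else z ~ member
  fit <- lm(form, data = d)
  cf <- summary(fit)$coefficients["member", ]
  data.frame(coefficient = cf[1], se = cf[2], t = cf[3],
             p = pt(cf[3], df = fit$df.residual, lower.tail = FALSE),
             n_set = length(moduleGenes), n_background = length(background),
             row.names = NULL)
}

#' Candidate genes from module membership plus gene-based significance
#'
#' Benjamini-Hochberg correction of the gene-based GWAS p-values over the
#' union of the selected modules' genes (or per module); genes that stay
#' significant and lie outside every risk locus are the network + GWAS
#' candidates.
#'
#' @param gwas data.frame with `gene` and `p`.
#' @param selectedModules named list of gene vectors (module label ->
#'   genes).
#' @param tads a [TadAnnotation-class].
#' @param alpha adjusted-p threshold (default 0.05).
#' @param perModule apply BH within each module separately instead of over
#'   the union (default FALSE).
#' @return data.frame: gene, module, p, padj, outside_tad; candidates are
#'   the rows with `padj < alpha & outside_tad`.
#' @export
moduleGeneFdr <- function(gwas, selectedModules, tads, alpha = 0.05,
                          perModule = FALSE) {
  tab <- do.call(rbind, lapply(names(selectedModules), function(m)
    data.frame(gene = selectedModules[[m]], module = m,
               stringsAsFactors = FALSE)))
  tab <- tab[!duplicated(tab$gene), , drop = FALSE]
  tab$p <- gwas$p[match(tab$gene, gwas$gene)]
  tab <- tab[!is.na(tab$p), , drop = FALSE]
  if (!nrow(tab)) {
    warning("no module gene has a GWAS entry")
    return(data.frame(gene = character(0), module = character(0),
                      p = numeric(0), padj = numeric(0),
                      outside_tad = logical(0), candidate = logical(0)))
  }
  tab$padj <- if (perModule)
    stats::ave(tab$p, tab$module, FUN = function(p) p.adjust(p, "BH"))
  else p.adjust(tab$p, "BH")
  tab$outside_tad <- !tab$gene %in% tadGenes(tads)
  tab$candidate <- tab$padj < alpha & tab$outside_tad
  tab[order(tab$padj, tab$gene), , drop = FALSE]
}

#' Score-correlation candidate lists inside and outside risk loci
#'
#' From per-gene score correlations, list A holds genes with `r >
#' threshold` inside loci but outside the disease set (locus-level
#' candidates), list B genes with `r > threshold` outside every locus
#' (novel candidates); both sorted by decreasing r.
#'
#' @param geneCor data.frame from [correlateScoreWithGenes()].
#' @param tads a [TadAnnotation-class].
#' @param geneSet the disease [WeightedGeneSet-class].
#' @param rThreshold correlation threshold (default 0.01).
#' @return list with data.frames `tadGene` and `gene` (columns gene, r).
#' @export
scoreCorrelationCandidates <- function(geneCor, tads, geneSet,
                                       rThreshold = 0.01) {
  pos <- geneCor[geneCor$r > rThreshold, , drop = FALSE]
  tg <- tadGenes(tads)
  inSet <- pos$gene %in% geneIds(geneSet)
  inTad <- pos$gene %in% tg
  listA <- pos[inTad & !inSet, c("gene", "r"), drop = FALSE]
  listB <- pos[!inTad, c("gene", "r"), drop = FALSE]
  listA <- listA[order(-listA$r, listA$gene), , drop = FALSE]
  listB <- listB[order(-listB$r, listB$gene), , drop = FALSE]
  rownames(listA) <- rownames(listB) <- NULL
  list(tadGene = listA, gene = listB)
}

#' Assemble the candidate table across prioritization approaches
#'
#' Long-format table with one row per (gene, approach): `DEG` (up-DEGs of
#' the associated subcluster inside loci, outside the disease set),
#' `scDRS-TAD-gene` and `scDRS-gene` (score-correlation lists), and
#' `hdWGCNA+GWAS` (module genes significant in the gene-based test outside
#' loci). The top 10 per approach are marked, and genes outside both the
#' disease set and the loci are flagged novel.
#'
#' @param degCandidates `candidates` data.frame from
#'   [overlapWithAnnotation()].
#' @param scdrsLists list from [scoreCorrelationCandidates()].
#' @param moduleFdr data.frame from [moduleGeneFdr()].
#' @param geneSet the disease [WeightedGeneSet-class].
#' @param tads a [TadAnnotation-class].
#' @return data.frame: gene, approach, evidence, value, module, top10,
#'   novel.
#' @export
assembleCandidateTable <- function(degCandidates, scdrsLists, moduleFdr,
                                   geneSet, tads) {
  rows <- list()
  if (nrow(degCandidates))
    rows$deg <- data.frame(gene = degCandidates$gene, approach = "DEG",
                           evidence = "log2fc", value = degCandidates$log2fc,
                           module = NA_character_,
                           stringsAsFactors = FALSE)
  if (nrow(scdrsLists$tadGene))
    rows$sta <- data.frame(gene = scdrsLists$tadGene$gene,
                           approach = "scDRS-TAD-gene", evidence = "r",
                           value = scdrsLists$tadGene$r,
                           module = NA_character_, stringsAsFactors = FALSE)
  if (nrow(scdrsLists$gene))
    rows$sg <- data.frame(gene = scdrsLists$gene$gene,
                          approach = "scDRS-gene", evidence = "r",
                          value = scdrsLists$gene$r,
                          module = NA_character_, stringsAsFactors = FALSE)
  mf <- moduleFdr[moduleFdr$candidate, , drop = FALSE]
  if (nrow(mf))
    rows$hw <- data.frame(gene = mf$gene, approach = "hdWGCNA+GWAS",
                          evidence = "padj", value = mf$padj,
                          module = as.character(mf$module),
                          stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(gene = character(0), approach = character(0),
                      evidence = character(0), value = numeric(0),
                      module = character(0), top10 = logical(0),
                      novel = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$top10 <- stats::ave(seq_len(nrow(out)), out$approach,
                          FUN = seq_along) <= 10
  out$novel <- !out$gene %in% geneIds(geneSet) &
    !out$gene %in% tadGenes(tads)
  out
}
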