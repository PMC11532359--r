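#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats cor sd var quantile rnorm rlnorm rnbinom runif pnorm pt
#'   p.adjust phyper prcomp lm coef setNames loess predict ks.test
#'   hclust cutree as.dist median reformulate ave
#' @importFrom utils head read.table write.table combn
NULL

#' Gene set with per-gene weights
#'
#' A named collection of gene identifiers, each carrying a positive weight.
#' Unweighted sets simply carry weight 1 for every gene; the weighted setting
#' uses gene-based GWAS z-scores as weights.
#'
#' @slot name single character, the set label.
#' @slot genes character vector of unique gene identifiers.
#' @slot weights numeric vector parallel to `genes`; finite and positive.
#'
#' @aliases WeightedGeneSet-class
#' @exportClass WeightedGeneSet
setClass("WeightedGeneSet",
  representation(name = "character", genes = "character", weights = "numeric"))

setValidity("WeightedGeneSet", function(object) {
  msg <- NULL
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be a single string")
  if (anyDuplicated(object@genes))
    msg <- c(msg, paste0("duplicate gene identifiers: ",
      paste(unique(object@genes[duplicated(object@genes)]), collapse = ", ")))
  if (length(object@weights) != length(object@genes))
    msg <- c(msg, "'weights' must align 1:1 with 'genes'")
  if (length(object@weights) && (!all(is.finite(object@weights)) ||
      any(object@weights < 0)))
    msg <- c(msg, "weights must be finite and non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Construct a WeightedGeneSet
#'
#' @param genes character vector of gene identifiers.
#' @param weights numeric weights, recycled default 1 (unweighted setting).
#' @param name set label.
#' @return A [WeightedGeneSet-class] object.
#' @examples
#' gs <- WeightedGeneSet(c("A", "B"), weights = c(2, 1), name = "risk")
#' geneIds(gs)
#' @export
WeightedGeneSet <- function(genes, weights = rep(1, length(genes)),
                            name = "geneset") {
  new("WeightedGeneSet", name = name, genes = as.character(genes),
      weights = as.numeric(weights))
}

#' @describeIn WeightedGeneSet gene identifiers of a set.
#' @param x a `WeightedGeneSet`.
#' @export
geneIds <- function(x) x@genes

#' @describeIn WeightedGeneSet per-gene weights, named by gene.
#' @export
geneWeights <- function(x) setNames(x@weights, x@genes)

#' @describeIn WeightedGeneSet set label.
#' @export
setName <- function(x) x@name

setMethod("show", "WeightedGeneSet", function(object) {
  cat("WeightedGeneSet '", object@name, "' with ", length(object@genes),
      " genes\n", sep = "")
  w <- object@weights
  if (length(w) && !all(w == w[1]))
    cat("  weights in [", format(min(w), digits = 3), ", ",
        format(max(w), digits = 3), "]\n", sep = "")
  else cat("  unweighted (all weights ", if (length(w)) w[1] else 1, ")\n",
           sep = "")
})

#' Risk-locus (TAD) annotation
#'
#' Genomic intervals of topologically associating domains overlapping GWAS
#' risk loci, together with a gene-to-locus assignment. Genes absent from the
#' map are "outside TADs". Intervals are imported from BED (0-based
#' half-open on disk; stored 1-based closed as GRanges).
#'
#' @slot loci a [GenomicRanges::GRanges] with a `locus_id` metadata column.
#' @slot geneMap named character; names are gene identifiers, values locus ids.
#'
#' @aliases TadAnnotation-class
#' @exportClass TadAnnotation
setClass("TadAnnotation",
  representation(loci = "GRanges", geneMap = "character"))

setValidity("TadAnnotation", function(object) {
  msg <- NULL
  ids <- object@loci$locus_id
  if (is.null(ids)) msg <- c(msg, "'loci' must carry a 'locus_id' column")
  if (anyDuplicated(names(object@geneMap)))
    msg <- c(msg, "a gene maps to more than one locus")
  if (length(object@geneMap) && !all(object@geneMap %in% ids))
    msg <- c(msg, paste0("genes mapped to unknown locus ids: ",
      paste(unique(object@geneMap[!object@geneMap %in% ids]), collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' Construct a TadAnnotation
#'
#' @param loci `GRanges` with `locus_id` metadata column.
#' @param geneMap named character vector gene -> locus id (may be empty).
#' @return A [TadAnnotation-class] object.
#' @export
TadAnnotation <- function(loci, geneMap = character(0)) {
  new("TadAnnotation", loci = loci, geneMap = geneMap)
}

#' @describeIn TadAnnotation locus intervals as GRanges.
#' @param x a `TadAnnotation`.
#' @export
tadLoci <- function(x) x@loci

#' @describeIn TadAnnotation named gene -> locus id map.
#' @export
tadGeneMap <- function(x) x@geneMap

#' @describeIn TadAnnotation identifiers of all genes inside any locus.
#' @export
tadGenes <- function(x) names(x@geneMap)

setMethod("show", "TadAnnotation", function(object) {
  cat("TadAnnotation with", length(object@loci), "loci and",
      length(object@geneMap), "mapped genes\n")
})

#' Per-cell disease-relevance scores
#'
#' Raw and normalized per-cell scores for a weighted gene set, empirical
#' p-values against pooled matched-control scores, BH FDR, and the
#' normalized control scores themselves (cells x control sets), which the
#' group-level Monte Carlo tests reuse.
#'
#' @slot cells character, cell identifiers (column names of the scored data).
#' @slot raw numeric raw weighted-mean scores.
#' @slot normalized numeric control-normalized scores.
#' @slot pval numeric pooled empirical p-values in (0, 1].
#' @slot fdr numeric BH-adjusted p-values.
#' @slot controls numeric matrix (cells x B) of normalized control scores.
#'
#' @aliases CellScores-class
#' @exportClass CellScores
setClass("CellScores",
  representation(cells = "character", raw = "numeric", normalized = "numeric",
                 pval = "numeric", fdr = "numeric", controls = "matrix"))

setValidity("CellScores", function(object) {
  n <- length(object@cells)
  msg <- NULL
  if (length(object@raw) != n || length(object@normalized) != n ||
      length(object@pval) != n || length(object@fdr) != n)
    msg <- c(msg, "score vectors must match the number of cells")
  if (nrow(object@controls) != n)
    msg <- c(msg, "'controls' must have one row per cell")
  if (n && (any(object@pval <= 0) || any(object@pval > 1)))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn CellScores scores as a data.frame (cell, raw, normalized,
#'   pval, fdr).
#' @param x a `CellScores`.
#' @export
scoreTable <- function(x) {
  data.frame(cell = x@cells, raw = x@raw, normalized = x@normalized,
             pval = x@pval, fdr = x@fdr, row.names = NULL)
}

#' @describeIn CellScores matrix of normalized control scores (cells x B).
#' @export
controlScores <- function(x) x@controls

#' @describeIn CellScores normalized per-cell scores, named by cell.
#' @export
normalizedScores <- function(x) setNames(x@normalized, x@cells)

#' @describeIn CellScores pooled empirical p-values, named by cell.
#' @export
scorePvals <- function(x) setNames(x@pval, x@cells)

setMethod("show", "CellScores", function(object) {
  cat("CellScores for", length(object@cells), "cells,",
      ncol(object@controls), "control sets\n")
  cat("  normalized score range: [",
      format(min(object@normalized), digits = 3), ", ",
      format(max(object@normalized), digits = 3), "]\n", sep = "")
  cat(" ", sum(object@fdr < 0.1), "cells at FDR < 0.1\n")
})

#' Metacell expression matrix
#'
#' Aggregated expression over groups of k nearest-neighbor cells from one
#' cell group, used to de-noise gene-gene correlations before network
#' construction. Expression is the log1p depth-normalized sum of member-cell
#' counts.
#'
#' @slot expr numeric matrix, genes x metacells.
#' @slot members list of integer vectors; member cell indices per metacell.
#' @slot cells character, identifiers of the cells indexed by `members`.
#' @slot group character, the source cell group label.
#' @slot k integer, cells aggregated per metacell.
#'
#' @aliases Metacells-class
#' @exportClass Metacells
setClass("Metacells",
  representation(expr = "matrix", members = "list", cells = "character",
                 group = "character", k = "integer"))

setValidity("Metacells", function(object) {
  msg <- NULL
  if (length(object@members) != ncol(object@expr))
    msg <- c(msg, "'members' must have one entry per metacell")
  if (length(object@members) &&
      !all(lengths(object@members) == object@k))
    msg <- c(msg, "every metacell must aggregate exactly k cells")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn Metacells genes x metacells expression matrix.
#' @param x a `Metacells`.
#' @export
metacellExpr <- function(x) x@expr

#' @describeIn Metacells list of member cell identifiers per metacell.
#' @export
metacellMembers <- function(x) lapply(x@members, function(i) x@cells[i])

setMethod("show", "Metacells", function(object) {
  cat("Metacells:", ncol(object@expr), "metacells of k =", object@k,
      "cells from group '", object@group, "' (", nrow(object@expr),
      " genes)\n", sep = " ")
})

#' Co-expression module assignment
#'
#' Gene-to-module labels (0 = unassigned), per-module eigengenes over
#' metacells, eigengene-based connectivity (kME) for every gene x module,
#' and per-module hub genes (top own-module kME).
#'
#' @slot genes character, gene identifiers.
#' @slot labels integer module label per gene; 0 means unassigned.
#' @slot eigengenes numeric matrix, metacells x modules; unit-norm columns
#'   sign-oriented to correlate positively with module mean expression.
#' @slot kme numeric matrix, genes x modules, Pearson correlation of each
#'   gene with each module eigengene.
#' @slot hubGenes list of character vectors, top kME genes per module.
#' @slot power numeric, the soft power used to build the network.
#'
#' @aliases ModuleSet-class
#' @exportClass ModuleSet
setClass("ModuleSet",
  representation(genes = "character", labels = "integer",
                 eigengenes = "matrix", kme = "matrix", hubGenes = "list",
                 power = "numeric"))

setValidity("ModuleSet", function(object) {
  msg <- NULL
  if (length(object@labels) != length(object@genes))
    msg <- c(msg, "'labels' must align with 'genes'")
  if (any(object@labels < 0L))
    msg <- c(msg, "labels must be >= 0 (0 = unassigned)")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ModuleSet named integer vector of module labels (0 =
#'   unassigned).
#' @param x a `ModuleSet`.
#' @export
moduleLabels <- function(x) setNames(x@labels, x@genes)

#' @describeIn ModuleSet list of gene vectors per module, named by label.
#' @export
moduleGenes <- function(x) {
  labs <- sort(unique(x@labels[x@labels > 0L]))
  setNames(lapply(labs, function(l) x@genes[x@labels == l]),
           as.character(labs))
}

#' @describeIn ModuleSet metacells x modules eigengene matrix.
#' @export
moduleEigengenes <- function(x) x@eigengenes

#' @describeIn ModuleSet genes x modules kME matrix.
#' @export
moduleKME <- function(x) x@kme

#' @describeIn ModuleSet list of hub genes per module.
#' @export
hubGenes <- function(x) x@hubGenes

setMethod("show", "ModuleSet", function(object) {
  k <- length(unique(object@labels[object@labels > 0L]))
  cat("ModuleSet:", k, "modules over", length(object@genes),
      "genes (", sum(object@labels == 0L), "unassigned ), soft power",
      object@power, "\n")
  if (k) {
    sz <- table(object@labels[object@labels > 0L])
    cat("  module sizes:", paste(sz, collapse = ", "), "\n")
  }
})
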