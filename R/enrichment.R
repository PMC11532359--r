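#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of a gene list against every term of a
#' term-to-gene map: `P(X >= k)` with background size N, term size K, list
#' size n and overlap k, equivalent to a one-sided Fisher exact test on
#' the 2x2 table. Term genes are intersected with the background; terms
#' with zero overlap are not tested. BH correction across tested terms.
#'
#' @param geneList character vector (subset of `background`).
#' @param termMap named list of gene vectors or [WeightedGeneSet-class]
#'   objects.
#' @param background character vector, the gene universe (typically all
#'   genes tested in the expression matrix).
#' @return data.frame: term, overlap, term_size, list_size,
#'   background_size, p, padj, genes (comma-separated overlap).
#' @export
overrepresentationTest <- function(geneList, termMap, background) {
  if (!length(background)) stop("empty background")
  geneList <- intersect(geneList, background)
  n <- length(geneList)
  N <- length(background)
  rows <- lapply(names(termMap), function(tn) {
    tg <- termMap[[tn]]
    if (methods::is(tg, "WeightedGeneSet")) tg <- geneIds(tg)
    tg <- intersect(tg, background)
    ov <- intersect(tg, geneList)
    if (!length(ov)) return(NULL)
    K <- length(tg); k <- length(ov)
    data.frame(term = tn, overlap = k, term_size = K, list_size = n,
               background_size = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term = character(0), overlap = integer(0),
                      term_size = integer(0), list_size = integer(0),
                      background_size = integer(0), p = numeric(0),
                      padj = numeric(0), genes = character(0)))
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, "BH")
  out <- out[order(out$p, out$term),
             c("term", "overlap", "term_size", "list_size",
               "background_size", "p", "padj", "genes")]
  rownames(out) <- NULL
  out
}

#' Collapse near-duplicate enriched terms (approximation)
#'
#' Optional post-processing: terms whose gene overlaps exceed a Jaccard
#' threshold are grouped and only the smallest-p term of each group is
#' kept. This is a set-overlap approximation, not an ontology-aware
#' redundancy reduction.
#'
#' @param enrichment output of [overrepresentationTest()].
#' @param termMap the same term-to-gene map.
#' @param jaccard collapse threshold (default 0.8).
#' @return The filtered enrichment table.
#' @export
collapseRedundantTerms <- function(enrichment, termMap, jaccard = 0.8) {
  if (nrow(enrichment) < 2) return(enrichment)
  sets <- lapply(enrichment$term, function(tn) {
    tg <- termMap[[tn]]
    if (methods::is(tg, "WeightedGeneSet")) geneIds(tg) else tg
  })
  keep <- rep(TRUE, nrow(enrichment))
  for (i in seq_along(sets)) {       # rows are p-sorted: earlier wins
    if (!keep[i]) next
    for (j in seq_along(sets)) {
      if (j <= i || !keep[j]) next
      inter <- length(intersect(sets[[i]], sets[[j]]))
      un <- length(union(sets[[i]], sets[[j]]))
      if (un > 0 && inter / un > jaccard) keep[j] <- FALSE
    }
  }
  enrichment[keep, , drop = FALSE]
}
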