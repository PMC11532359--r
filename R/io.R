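#' Read a single-cell count matrix
#'
#' Reads a MatrixMarket coordinate file plus gene / barcode identifier lists
#' and a cell-metadata table into a [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment-class]
#' with a `counts` assay. Metadata rows are joined to cells by barcode.
#'
#' @param mtxPath path to the `.mtx` coordinate file (genes x cells).
#' @param genesPath one gene identifier per line (first column if tabbed).
#' @param barcodesPath one cell barcode per line.
#' @param metadataPath optional TSV with a header; must contain a `barcode`
#'   column plus e.g. `sample` and `cell_type`.
#' @return A `SingleCellExperiment` with sparse integer `counts`.
#' @export
readCounts <- function(mtxPath, genesPath, barcodesPath, metadataPath = NULL) {
  m <- methods::as(Matrix::readMM(mtxPath), "CsparseMatrix")
  genes <- read.table(genesPath, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  barcodes <- read.table(barcodesPath, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes))
    stop("dimension mismatch: ", mtxPath, " declares ", nrow(m),
         " rows but ", genesPath, " lists ", length(genes), " genes")
  if (ncol(m) != length(barcodes))
    stop("dimension mismatch: ", mtxPath, " declares ", ncol(m),
         " columns but ", barcodesPath, " lists ", length(barcodes),
         " barcodes")
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers in ", genesPath, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  dimnames(m) <- list(genes, barcodes)
  cd <- S4Vectors::DataFrame(row.names = barcodes)
  if (!is.null(metadataPath)) {
    md <- read.table(metadataPath, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    if (!"barcode" %in% colnames(md))
      stop("metadata file ", metadataPath, " lacks a 'barcode' column")
    idx <- match(barcodes, md$barcode)
    if (anyNA(idx))
      stop("metadata file ", metadataPath, " is missing ",
           sum(is.na(idx)), " barcodes")
    cd <- S4Vectors::DataFrame(md[idx, setdiff(colnames(md), "barcode"),
                                  drop = FALSE], row.names = barcodes)
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), colData = cd)
}

#' Write a count matrix and metadata to disk
#'
#' Inverse of [readCounts()]: writes `matrix.mtx`, `genes.tsv`,
#' `barcodes.tsv` and `metadata.tsv` into a directory.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeCounts <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(m, "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(sce), file.path(dir, "genes.tsv"))
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  md <- as.data.frame(SummarizedExperiment::colData(sce))
  md <- cbind(barcode = colnames(sce), md)
  writeTsv(md, file.path(dir, "metadata.tsv"))
  invisible(dir)
}

#' Read a gene set, GMT or two/three-column TSV
#'
#' A `.gmt` file yields one [WeightedGeneSet-class] per line (weights 1,
#' the unweighted setting). A TSV needs columns set name, gene and
#' optionally a weight column. Duplicate genes keep their first occurrence
#' with a warning.
#'
#' @param path input file.
#' @param weightColumn index of the TSV weight column (default 3); `NA` or a
#'   missing column means unweighted.
#' @return A `WeightedGeneSet` (TSV) or list of them (GMT with > 1 line).
#' @export
readGeneSet <- function(path, weightColumn = 3) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    sets <- readGmt(path)
    if (length(sets) == 1L) return(sets[[1]]) else return(sets)
  }
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("gene-set TSV needs at least 2 columns")
  genes <- as.character(tab[[2]])
  weights <- if (!is.na(weightColumn) && ncol(tab) >= weightColumn)
    as.numeric(tab[[weightColumn]]) else rep(1, length(genes))
  bad <- !is.finite(weights) | weights < 0
  if (any(bad))
    stop("non-finite or negative weight for gene(s): ",
         paste(genes[bad], collapse = ", "))
  if (anyDuplicated(genes)) {
    warning("duplicate genes in ", path, "; keeping first occurrence: ",
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
    keep <- !duplicated(genes)
    genes <- genes[keep]; weights <- weights[keep]
  }
  WeightedGeneSet(genes, weights, name = as.character(tab[[1]][1]))
}

#' Read a GMT term-to-gene map
#'
#' @param path a `.gmt` file: set name, description, then gene ids, tabbed.
#' @return Named list of [WeightedGeneSet-class] objects (all weights 1).
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in GMT set ", f[1], "; keeping first")
      genes <- genes[!duplicated(genes)]
    }
    WeightedGeneSet(genes, name = f[1])
  })
  setNames(sets, vapply(sets, setName, character(1)))
}

#' Write gene sets as GMT
#'
#' @param sets a `WeightedGeneSet` or list of them.
#' @param path output `.gmt` path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path) {
  if (methods::is(sets, "WeightedGeneSet")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(setName(s), "na", geneIds(s)), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a weighted gene set as a three-column TSV
#'
#' @param set a `WeightedGeneSet`.
#' @param path output path; columns set, gene, weight (no header).
#' @return `path`, invisibly.
#' @export
writeGeneSet <- function(set, path) {
  tab <- data.frame(set = setName(set), gene = geneIds(set),
                    weight = unname(geneWeights(set)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a risk-locus (TAD) annotation
#'
#' Intervals come from a BED file (0-based half-open; the BED `name` field
#' is the locus id). The gene map is a two-column TSV (gene, locus id, no
#' header).
#'
#' @param bedPath BED file of locus intervals.
#' @param geneMapPath gene -> locus TSV; `NULL` for an empty map.
#' @return A [TadAnnotation-class].
#' @export
readTads <- function(bedPath, geneMapPath = NULL) {
  gr <- rtracklayer::import(bedPath, format = "BED")
  if (is.null(gr$name) || anyNA(gr$name))
    stop("BED file ", bedPath, " must carry locus ids in the name field")
  gr$locus_id <- gr$name
  geneMap <- character(0)
  if (!is.null(geneMapPath)) {
    gm <- read.table(geneMapPath, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    if (nrow(gm)) {
      if (anyDuplicated(gm[[1]])) {
        warning("genes mapped more than once; keeping first occurrence")
        gm <- gm[!duplicated(gm[[1]]), , drop = FALSE]
      }
      unknown <- !gm[[2]] %in% gr$locus_id
      if (any(unknown))
        stop("genes mapped to unknown locus id(s): ",
             paste(unique(gm[[2]][unknown]), collapse = ", "))
      geneMap <- setNames(as.character(gm[[2]]), gm[[1]])
    }
  }
  TadAnnotation(gr, geneMap)
}

#' Write a TAD annotation
#'
#' @param tads a `TadAnnotation`.
#' @param bedPath output BED path (0-based half-open).
#' @param geneMapPath output gene-map TSV path.
#' @return `bedPath`, invisibly.
#' @export
writeTads <- function(tads, bedPath, geneMapPath) {
  gr <- tadLoci(tads)
  gr$name <- gr$locus_id
  gr$score <- 0
  rtracklayer::export(gr, bedPath, format = "BED")
  gm <- tadGeneMap(tads)
  write.table(data.frame(gene = names(gm), locus = unname(gm)),
              geneMapPath, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(bedPath)
}

#' Read a gene-based GWAS statistics table
#'
#' A TSV with header columns `gene`, `z` and `p` (additional columns such
#' as covariates are kept).
#'
#' @param path input TSV.
#' @return data.frame with one row per gene.
#' @export
readGwas <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  need <- c("gene", "z", "p")
  if (!all(need %in% colnames(tab)))
    stop("GWAS table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  if (anyDuplicated(tab$gene))
    stop("duplicate genes in GWAS table: ",
         paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "))
  tab
}

#' Write a gene-based GWAS statistics table
#'
#' @param gwas data.frame with `gene`, `z`, `p` columns.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeGwas <- function(gwas, path) {
  writeTsv(gwas, path)
  invisible(path)
}

#' Split genes by detection in a count matrix
#'
#' A gene is detected when it is present among the matrix gene identifiers
#' and has total count > 0 (the stricter reading of "not detected";
#' `zeroCountsUndetected = FALSE` keeps the identifier-presence-only rule).
#'
#' @param genes character vector of gene identifiers to partition.
#' @param sce `SingleCellExperiment` with a `counts` assay.
#' @param zeroCountsUndetected treat all-zero genes as undetected (default).
#' @return list with `detected` and `undetected` character vectors; their
#'   union is `genes`, their intersection empty.
#' @export
filterDetectedGenes <- function(genes, sce, zeroCountsUndetected = TRUE) {
  genes <- as.character(genes)
  present <- genes %in% rownames(sce)
  det <- present
  if (zeroCountsUndetected && any(present)) {
    tot <- Matrix::rowSums(
      SummarizedExperiment::assay(sce, "counts")[genes[present], ,
                                                 drop = FALSE])
    det[present] <- tot > 0
  }
  list(detected = genes[det], undetected = genes[!det])
}

# Shared TSV writer: header row, no quoting, deterministic formatting.
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
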