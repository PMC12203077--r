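#' Construct a DiscDataSet
#'
#' @param counts genes x cells matrix of non-negative integer counts (dense
#'   base matrix or any \pkg{Matrix} sparse matrix).
#' @param geneIds,cellIds identifiers; default to the dimnames of
#'   \code{counts}.
#' @param individuals optional per-cell individual labels (length =
#'   number of cells).  When given, cells are reordered so that each
#'   individual's cells are contiguous, individuals sorted
#'   lexicographically (the canonical order used throughout, so permutation
#'   seeds reproduce across runs).
#' @return A \linkS4class{DiscDataSet}.
#' @export
DiscDataSet <- function(counts, geneIds = rownames(counts),
                        cellIds = colnames(counts), individuals = NULL) {
  if (is.null(geneIds)) geneIds <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(cellIds)) cellIds <- paste0("cell", seq_len(ncol(counts)))
  if (length(geneIds) != nrow(counts))
    .discStop("validation", sprintf(
      "dimension mismatch: %d gene ids but %d matrix rows", length(geneIds), nrow(counts)))
  if (length(cellIds) != ncol(counts))
    .discStop("validation", sprintf(
      "dimension mismatch: %d cell ids but %d matrix columns", length(cellIds), ncol(counts)))
  dimnames(counts) <- list(as.character(geneIds), as.character(cellIds))
  sce <- SingleCellExperiment::SingleCellExperiment(assays = list(counts = counts))
  dds <- methods::new("DiscDataSet", sce)
  if (!is.null(individuals)) {
    if (length(individuals) != ncol(counts))
      .discStop("validation", "individuals must have one entry per cell")
    SummarizedExperiment::colData(dds)$individual <- as.character(individuals)
    dds <- .canonicalizeCells(dds)
  }
  methods::validObject(dds)
  dds
}

# Reorder cells so individuals are contiguous and lexicographically sorted;
# within an individual the original cell order is preserved.
.canonicalizeCells <- function(dds) {
  ind <- SummarizedExperiment::colData(dds)$individual
  ord <- order(ind, seq_along(ind), method = "radix")
  if (!identical(ord, seq_along(ind))) dds <- dds[, ord]
  SummarizedExperiment::colData(dds)$individual <-
    factor(SummarizedExperiment::colData(dds)$individual)
  dds
}

#' @describeIn DiscDataSet-class Per-cell individual labels (factor, levels
#'   in canonical sorted order), or NULL when not yet attached.
#' @param dds a DiscDataSet.
#' @export
individualOf <- function(dds) {
  cd <- SummarizedExperiment::colData(dds)
  if (!"individual" %in% colnames(cd)) return(NULL)
  ind <- cd$individual
  if (!is.factor(ind)) ind <- factor(ind)
  ind
}

#' @describeIn DiscDataSet-class Sorted unique individual identifiers.
#' @export
individualIds <- function(dds) levels(individualOf(dds))

#' @describeIn DiscDataSet-class Number of cells per individual (named
#'   integer vector).
#' @export
cellsPerIndividual <- function(dds) {
  ind <- individualOf(dds)
  if (is.null(ind)) .discStop("validation", "no individual assignment; call attachIndividuals() first")
  table(ind)
}

setMethod("show", "DiscDataSet", function(object) {
  ind <- individualOf(object)
  cat(sprintf("DiscDataSet: %d genes x %d cells", nrow(object), ncol(object)))
  if (!is.null(ind)) cat(sprintf(", %d individuals", nlevels(ind)))
  cat(if ("normcounts" %in% SummarizedExperiment::assayNames(object)) " (normalized)\n" else "\n")
})

# ---------------------------------------------------------------------------
# I/O

.readIdFile <- function(path, what) {
  if (!file.exists(path)) .discStop("io", sprintf("%s file not found: %s", what, path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) .discStop("io", sprintf("%s file is empty: %s", what, path))
  ids <- if (grepl("[\t,]", first)) {
    sep <- if (grepl("\t", first)) "\t" else ","
    tab <- utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                             comment.char = "", quote = "\"")
    as.character(tab[[1L]])
  } else {
    readLines(path)
  }
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids))
    .discStop("validation", sprintf("duplicate identifiers in %s file %s", what, path))
  ids
}

.readDenseMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, sep = sep, header = FALSE)
  as.matrix(tab)
}

#' Read a count matrix with gene and cell identifier files
#'
#' The matrix file may be Matrix Market coordinate format (as written by
#' e.g. CellRanger or \code{\link{writeCounts}}) or dense delimited text.
#' Orientation is fixed to genes-in-rows: if the dimensions only match the
#' identifier files after transposition the matrix is transposed with a
#' warning.  A square matrix with equally many gene and cell ids is taken
#' as genes-in-rows, with a warning about the ambiguity.
#'
#' @param pathMatrix,pathGenes,pathCells file paths.  Identifier files are
#'   either one id per line or delimited with a header row (first column
#'   used).
#' @return A \linkS4class{DiscDataSet} without individual assignment.
#' @export
readCounts <- function(pathMatrix, pathGenes, pathCells) {
  if (!file.exists(pathMatrix)) .discStop("io", sprintf("matrix file not found: %s", pathMatrix))
  first <- readLines(pathMatrix, n = 1L)
  isMM <- length(first) && grepl("^%%MatrixMarket", first)
  m <- if (isMM) {
    mm <- tryCatch(Matrix::readMM(pathMatrix),
                   error = function(e) .discStop("io", sprintf("cannot parse Matrix Market file %s: %s",
                                                               pathMatrix, conditionMessage(e))))
    if (Matrix::nnzero(mm) == 0L)
      .discStop("validation", sprintf("no entries in matrix file %s", pathMatrix))
    methods::as(mm, "CsparseMatrix")
  } else {
    dm <- .readDenseMatrix(pathMatrix)
    if (nrow(dm) == 0L || ncol(dm) == 0L)
      .discStop("validation", sprintf("no entries in matrix file %s", pathMatrix))
    dm
  }
  .checkCounts(m)
  genes <- .readIdFile(pathGenes, "gene")
  cells <- .readIdFile(pathCells, "cell")
  if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    if (nrow(m) == ncol(m) && length(genes) == length(cells))
      warning("square count matrix: assuming genes-in-rows")
  } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
    warning("matrix orientation is cells-in-rows; transposing to genes-in-rows")
    m <- t(m)
  } else {
    .discStop("validation", sprintf(
      "dimension mismatch: matrix is %d x %d but there are %d gene and %d cell ids",
      nrow(m), ncol(m), length(genes), length(cells)))
  }
  DiscDataSet(m, geneIds = genes, cellIds = cells)
}

#' Attach cell-to-individual assignments
#'
#' @param dds a \linkS4class{DiscDataSet}.
#' @param cellMeta data.frame with columns \code{cell_id} and
#'   \code{individual}.  Rows for cells absent from \code{dds} are ignored
#'   with a warning; a cell of \code{dds} missing from \code{cellMeta} is an
#'   error.
#' @return The data set with individuals attached and cells reordered to the
#'   canonical (lexicographic, contiguous-per-individual) layout.
#' @export
attachIndividuals <- function(dds, cellMeta) {
  need <- c("cell_id", "individual")
  if (!all(need %in% colnames(cellMeta)))
    .discStop("validation", "cellMeta must have columns 'cell_id' and 'individual'")
  cm <- cellMeta[!duplicated(cellMeta$cell_id), , drop = FALSE]
  idx <- match(colnames(dds), cm$cell_id)
  if (anyNA(idx)) {
    missing <- colnames(dds)[is.na(idx)]
    .discStop("validation", sprintf("cell(s) not found in metadata: %s%s",
                                    paste(utils::head(missing, 5L), collapse = ", "),
                                    if (length(missing) > 5L) ", ..." else ""))
  }
  extra <- setdiff(cm$cell_id, colnames(dds))
  if (length(extra))
    warning(sprintf("%d metadata row(s) for cells absent from the matrix were ignored", length(extra)))
  ind <- as.character(cm$individual[idx])
  if (anyNA(ind)) .discStop("validation", "missing individual labels in metadata")
  SummarizedExperiment::colData(dds)$individual <- ind
  dds <- .canonicalizeCells(dds)
  methods::validObject(dds)
  dds
}

#' Remove genes exceeding a sparsity threshold
#'
#' A gene is removed when its fraction of zero-count cells is strictly
#' greater than \code{maxSparsity} (so the default keeps genes expressed in
#' at least 20\% of cells; a gene at exactly the threshold is kept).  Gene
#' order is preserved.
#'
#' @param dds a \linkS4class{DiscDataSet}.
#' @param maxSparsity maximum tolerated zero fraction, in (0, 1].
#' @export
filterSparsity <- function(dds, maxSparsity = 0.8) {
  if (!is.numeric(maxSparsity) || maxSparsity <= 0 || maxSparsity > 1)
    .discStop("validation", "maxSparsity must be in (0, 1]")
  m <- SummarizedExperiment::assay(dds, "counts")
  sparsity <- 1 - .rowNonzero(m) / ncol(m)
  keep <- sparsity <= maxSparsity
  if (!any(keep))
    .discStop("validation", sprintf("all %d genes exceed %.0f%% sparsity", nrow(dds), 100 * maxSparsity))
  dds[keep, ]
}

#' Total-sum-scaling normalization
#'
#' Divides each cell's counts by that cell's total, yielding per-cell
#' proportions stored in the \code{"normcounts"} assay (each retained
#' column sums to one; zeros are preserved exactly).  Cells with zero total
#' count cannot be normalized and are dropped with a warning; if an
#' individual loses all of its cells this way, an error is raised.
#'
#' @param dds a \linkS4class{DiscDataSet}.
#' @export
normalizeTSS <- function(dds) {
  m <- SummarizedExperiment::assay(dds, "counts")
  tot <- Matrix::colSums(m)
  drop <- tot == 0
  if (any(drop)) {
    ind <- individualOf(dds)
    if (!is.null(ind)) {
      lost <- setdiff(levels(ind), unique(as.character(ind[!drop])))
      if (length(lost))
        .discStop("validation", sprintf(
          "individual(s) %s would lose all cells to zero-total filtering",
          paste(lost, collapse = ", ")))
    }
    warning(sprintf("dropping %d cell(s) with zero total count", sum(drop)))
    dds <- dds[, !drop]
    m <- SummarizedExperiment::assay(dds, "counts")
    tot <- tot[!drop]
    ind <- individualOf(dds)
    if (!is.null(ind)) SummarizedExperiment::colData(dds)$individual <- droplevels(ind)
  }
  nm <- if (methods::is(m, "sparseMatrix")) {
    methods::as(m %*% Matrix::Diagonal(x = 1 / tot), "CsparseMatrix")
  } else {
    storage.mode(m) <- "double"
    m * rep(1 / tot, rep(nrow(m), length(tot)))
  }
  dimnames(nm) <- dimnames(m)
  SummarizedExperiment::assay(dds, "normcounts") <- nm
  dds
}

#' Write a DiscDataSet as Matrix Market plus metadata text files
#'
#' Writes \code{matrix.mtx}, \code{genes.txt}, \code{cells.txt} and, when
#' individuals are attached, \code{cell_meta.tsv}; the exact inverse of
#' \code{\link{readCounts}} + \code{\link{attachIndividuals}}.
#'
#' @param dds a \linkS4class{DiscDataSet}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeCounts <- function(dds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- SummarizedExperiment::assay(dds, "counts")
  sp <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(rownames(dds), file.path(dir, "genes.txt"))
  writeLines(colnames(dds), file.path(dir, "cells.txt"))
  ind <- individualOf(dds)
  if (!is.null(ind)) {
    utils::write.table(
      data.frame(cell_id = colnames(dds), individual = as.character(ind)),
      file.path(dir, "cell_meta.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
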