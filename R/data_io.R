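#' Read a genes-by-cells count matrix
#'
#' Reads a non-negative expression matrix from MatrixMarket sparse format
#' (with one-column gene and barcode sidecar files) or dense delimited text
#' (header row = cell ids, first column = gene ids). The returned matrix is
#' always oriented genes-as-rows; \code{transpose = TRUE} declares that the
#' file on disk is cells-by-genes.
#'
#' @param path path to the matrix file (\code{.mtx}, \code{.csv} or
#'   \code{.tsv}; a \code{.gz} suffix is handled transparently for text).
#' @param format one of \code{"auto"}, \code{"mtx"}, \code{"csv"},
#'   \code{"tsv"}; \code{"auto"} infers from the file extension.
#' @param transpose logical; set \code{TRUE} when the on-disk layout is
#'   cells-by-genes.
#' @param genesPath,cellsPath sidecar files for \code{mtx} input; default to
#'   \code{genes.tsv} and \code{barcodes.tsv} next to the matrix.
#' @return a numeric genes x cells matrix with gene ids as rownames and cell
#'   ids as colnames, validated (non-negative, finite, unique identifiers).
#' @examples
#' sim <- simulateCounts(nGenes = 40, nCells = 12, nClusters = 2,
#'                       markersPerCluster = 5, seed = 1)
#' d <- tempfile(fileext = ".csv")
#' writeCountMatrix(sim$counts, d)
#' m <- readCountMatrix(d)
#' stopifnot(identical(dim(m), dim(sim$counts)))
#' @export
readCountMatrix <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                            transpose = FALSE,
                            genesPath = NULL, cellsPath = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub("\\.gz$", "", basename(path)))
    format <- if (grepl("\\.mtx$", ext)) "mtx"
      else if (grepl("\\.tsv$|\\.txt$", ext)) "tsv"
      else "csv"
  }
  if (format == "mtx") {
    genesPath <- genesPath %||% file.path(dirname(path), "genes.tsv")
    cellsPath <- cellsPath %||% file.path(dirname(path), "barcodes.tsv")
    if (!file.exists(genesPath)) stop("gene sidecar not found: ", genesPath)
    if (!file.exists(cellsPath)) stop("cell sidecar not found: ", cellsPath)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genesPath)
    cells <- readLines(cellsPath)
    if (transpose) m <- t(m)
    if (nrow(m) != length(genes)) {
      stop(sprintf("matrix has %d rows but %d gene ids", nrow(m), length(genes)))
    }
    if (ncol(m) != length(cells)) {
      stop(sprintf("matrix has %d columns but %d cell ids", ncol(m), length(cells)))
    }
    dimnames(m) <- list(genes, cells)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (transpose) m <- t(m)
  }
  .checkMatrix(m, "matrix")
  m
}

#' Write a count matrix
#'
#' Inverse of \code{\link{readCountMatrix}}: MatrixMarket plus \code{genes.tsv}
#' and \code{barcodes.tsv} sidecars, or dense delimited text with cell ids as
#' the header row and gene ids in the first column.
#'
#' @param m genes x cells matrix with dimnames.
#' @param path output matrix file.
#' @param format \code{"auto"}, \code{"mtx"}, \code{"csv"} or \code{"tsv"}.
#' @return the paths written, invisibly.
#' @export
writeCountMatrix <- function(m, path, format = c("auto", "mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx"
      else if (grepl("\\.tsv$|\\.txt$", path)) "tsv"
      else "csv"
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix must carry gene and cell identifiers as dimnames")
  }
  if (format == "mtx") {
    genesPath <- file.path(dirname(path), "genes.tsv")
    cellsPath <- file.path(dirname(path), "barcodes.tsv")
    Matrix::writeMM(Matrix::Matrix(unname(m), sparse = TRUE), path)
    writeLines(rownames(m), genesPath)
    writeLines(colnames(m), cellsPath)
    return(invisible(c(path, genesPath, cellsPath)))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write per-cell cluster labels
#'
#' Labels travel as two-column CSV (\code{cell_id,label}). Labels may be
#' arbitrary strings; \code{\link{labelsToInteger}} maps them to dense
#' integers for the metrics.
#'
#' @param path label CSV path.
#' @return for \code{readLabels}, a character vector of labels named by cell
#'   id.
#' @export
readLabels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("label file must have columns cell_id,label")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' @rdname readLabels
#' @param labels vector of labels, named by cell id (or \code{cellIds} given).
#' @param cellIds optional cell identifiers overriding \code{names(labels)}.
#' @export
writeLabels <- function(labels, path, cellIds = NULL) {
  ids <- cellIds %||% names(labels)
  if (is.null(ids)) stop("cell identifiers required (names or cellIds)")
  df <- data.frame(cell_id = ids, label = as.vector(labels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map arbitrary labels to dense integer cluster ids
#'
#' Deterministic mapping in order of first appearance; every cluster id in
#' 1..K is used. All clustering metrics are invariant to the particular
#' mapping, so only determinism matters.
#'
#' @param labels vector of labels (any atomic type).
#' @return integer vector in 1..K with a \code{levels} attribute recording
#'   the original label of each integer id.
#' @export
labelsToInteger <- function(labels) {
  labels <- as.character(labels)
  lev <- unique(labels)
  out <- match(labels, lev)
  attr(out, "levels") <- lev
  names(out) <- names(labels)
  out
}

#' Drop genes with no expression in any cell
#'
#' Removes all-zero rows, preserving the order of the surviving genes. The
#' identifiers of the removed genes are attached as the
#' \code{"removedGenes"} attribute. Idempotent.
#'
#' @param m validated genes x cells matrix.
#' @return the filtered matrix, with attribute \code{removedGenes}.
#' @export
filterUnexpressedGenes <- function(m) {
  .checkMatrix(m)
  keep <- rowSums(m != 0) > 0L
  if (!any(keep)) stop("empty matrix after filtering: no gene is expressed")
  removed <- rownames(m)[!keep] %||% character(0)
  out <- m[keep, , drop = FALSE]
  attr(out, "removedGenes") <- removed
  out
}
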