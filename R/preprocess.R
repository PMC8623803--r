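#' Library-size normalization: log2(1 + CPM)
#'
#' Scales every cell (column) to counts per million and applies
#' \code{log2(1 + .)}: \code{x_ij = log2(1 + 1e6 * z_ij / sum_i z_ij)}.
#' The transform is monotone within a cell, so the within-cell ordering of
#' gene expression is preserved, and it removes library-size differences
#' between cells.
#'
#' @param m genes x cells matrix of non-negative counts or expression.
#' @return matrix of the same shape and dimnames, entries >= 0.
#' @examples
#' m <- matrix(c(1, 3), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
#' # a 1-cell matrix is rejected; use >= 2 cells
#' m <- cbind(m, c1b = c(2, 2))
#' cpmLogNormalize(m)[, 1]  # log2(1 + 250000), log2(1 + 750000)
#' @export
cpmLogNormalize <- function(m) {
  .checkMatrix(m)
  libSizes <- colSums(m)
  if (any(libSizes <= 0)) {
    bad <- colnames(m)[libSizes <= 0] %||% which(libSizes <= 0)
    stop("cells with zero library size (drop them first): ",
         paste(bad, collapse = ", "))
  }
  x <- log2(1 + sweep(m, 2L, libSizes / 1e6, "/"))
  dimnames(x) <- dimnames(m)
  x
}

#' Select potential feature genes by mean and variance
#'
#' Marker genes are expected to be highly expressed in one cell type and
#' rare elsewhere, which makes them high-mean and high-variance across
#' cells. The rule: keep genes whose mean (across cells) is strictly greater
#' than the median of all gene means, then among those retain the
#' \code{ceiling(topPct\% of M)} genes with the largest sample variance.
#' Variance ties at the cutoff are broken by lower row index, so the
#' selection is deterministic.
#'
#' @param x normalized genes x cells matrix (see
#'   \code{\link{cpmLogNormalize}}).
#' @param topPct percentage of genes to keep by variance, in (0, 100].
#' @param relativeTo whether the \code{topPct} count is taken relative to
#'   all \code{M} genes (default) or to the mean-filtered subset.
#' @return sorted integer vector of row indices into \code{x}.
#' @export
selectFeatureGenes <- function(x, topPct = 5,
                               relativeTo = c("all", "filtered")) {
  .checkMatrix(x)
  relativeTo <- match.arg(relativeTo)
  if (!(topPct > 0 && topPct <= 100)) stop("topPct must be in (0, 100]")
  mu <- rowMeans(x)
  survivors <- which(mu > stats::median(mu))
  names(survivors) <- NULL
  if (length(survivors) < 2L) {
    stop("insufficient feature genes: fewer than 2 genes exceed the median mean")
  }
  v <- apply(x[survivors, , drop = FALSE], 1L, stats::var)
  base <- if (relativeTo == "all") nrow(x) else length(survivors)
  nKeep <- min(ceiling(topPct / 100 * base), length(survivors))
  ord <- order(-v, survivors)  # ties: lower row index first
  sort(survivors[ord[seq_len(nKeep)]])
}
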