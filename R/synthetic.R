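#' Simulate a zero-inflated count matrix with planted clusters
#'
#' Generates a genes x cells count matrix that mimics the structure of
#' droplet scRNA-seq data: cells are assigned to near-balanced clusters;
#' every gene gets a log-normal baseline mean; each cluster owns a disjoint
#' block of marker genes whose mean is up-shifted by
#' \code{2^markerLogFold} in that cluster only; counts are drawn
#' negative-binomial with gene-level dispersion and a per-cell library-size
#' factor; finally each count is zeroed independently with probability
#' \code{dropoutRate * exp(-mu / dropoutDecay)}, so lowly expressed entries
#' drop out more often (expression-dependent dropout). Deterministic given
#' the seed.
#'
#' @param nGenes,nCells,nClusters matrix dimensions and planted cluster
#'   count (defaults 2000 genes, 600 cells, 5 clusters).
#' @param markersPerCluster planted marker genes per cluster (default 50);
#'   marker blocks are pairwise disjoint and occupy the first
#'   \code{nClusters * markersPerCluster} rows.
#' @param markerLogFold log2 fold change of markers in their own cluster
#'   (default 2, i.e. a 4-fold mean shift).
#' @param dropoutRate maximal dropout probability in [0, 1) (default 0.6).
#' @param dropoutDecay mean-expression scale of the dropout decay, on the
#'   count-mean scale (default 1).
#' @param libSizeRange range of the uniform per-cell library-size factor
#'   (default c(0.7, 1.3)).
#' @param dispersion negative-binomial dispersion (default 0.3; the NB size
#'   parameter is 1/dispersion).
#' @param seed integer seed.
#' @return list with \code{counts} (named genes x cells integer-valued
#'   matrix), \code{labels} (integer cluster per cell, named by cell id),
#'   \code{markerSets} (per-cluster character vectors of planted marker
#'   gene ids), and \code{expectedZeroFraction} (closed-form expectation of
#'   the zero fraction under the generative model, averaging the NB zero
#'   probability and the dropout probability over the realized mean
#'   matrix).
#' @export
simulateCounts <- function(nGenes = 2000L, nCells = 600L, nClusters = 5L,
                           markersPerCluster = 50L, markerLogFold = 2,
                           dropoutRate = 0.6, dropoutDecay = 1,
                           libSizeRange = c(0.7, 1.3), dispersion = 0.3,
                           seed = 1L) {
  if (nClusters > nCells) stop("more clusters than cells")
  if (markersPerCluster * nClusters > nGenes) {
    stop("marker blocks exceed the gene count")
  }
  if (dropoutRate < 0 || dropoutRate >= 1) stop("dropoutRate must be in [0, 1)")
  geneIds <- sprintf("gene%04d", seq_len(nGenes))
  cellIds <- sprintf("cell%04d", seq_len(nCells))
  withr::with_seed(seed, {
    labels <- rep_len(seq_len(nClusters), nCells)
    baseMean <- rlnorm(nGenes, meanlog = 0, sdlog = 1)
    libFactor <- runif(nCells, libSizeRange[1L], libSizeRange[2L])
    mu <- outer(baseMean, libFactor)
    markerSets <- vector("list", nClusters)
    for (k in seq_len(nClusters)) {
      rows <- ((k - 1L) * markersPerCluster + 1L):(k * markersPerCluster)
      markerSets[[k]] <- geneIds[rows]
      mu[rows, labels == k] <- mu[rows, labels == k] * 2^markerLogFold
    }
    counts <- matrix(rnbinom(nGenes * nCells, mu = mu, size = 1 / dispersion),
                     nGenes, nCells)
    pDrop <- dropoutRate * exp(-mu / dropoutDecay)
    dropped <- matrix(runif(nGenes * nCells) < pDrop, nGenes, nCells)
    counts[dropped] <- 0L
  })
  pNbZero <- (1 + mu * dispersion)^(-1 / dispersion)
  expectedZero <- mean(pNbZero + (1 - pNbZero) * pDrop)
  dimnames(counts) <- list(geneIds, cellIds)
  names(markerSets) <- paste0("cluster", seq_len(nClusters))
  list(counts = counts,
       labels = stats::setNames(as.integer(labels), cellIds),
       markerSets = markerSets,
       expectedZeroFraction = expectedZero)
}

#' Planted marker gene sets of a simulation
#'
#' Convenience accessor returning the per-cluster planted marker blocks of
#' a \code{\link{simulateCounts}} draw; these serve as ground-truth
#' differentially expressed gene sets in the agreement metrics.
#'
#' @param sim a list returned by \code{\link{simulateCounts}}.
#' @return named list of character vectors (pairwise disjoint).
#' @export
markerGeneSets <- function(sim) {
  if (is.null(sim$markerSets)) stop("not a simulateCounts result")
  sim$markerSets
}
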