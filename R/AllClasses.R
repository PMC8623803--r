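#' @import methods
#' @importFrom stats cor kmeans quantile rlnorm rnbinom runif sd var median pnorm setNames
#' @importFrom utils read.csv write.csv
NULL

#' K-nearest-neighbour cell graph from one similarity estimate
#'
#' Holds the binary, symmetric, zero-diagonal adjacency matrix of one
#' KNN similarity graph over cells, the Pearson-correlation weight pool of
#' its edges, and (after augmentation) the correlation threshold used to
#' rewrite edge membership.
#'
#' @slot adjacency N x N logical matrix, symmetric with zero diagonal.
#' @slot weightPool numeric vector of Pearson correlations on the KNN edges
#'   (one entry per undirected edge).
#' @slot threshold correlation threshold applied during augmentation
#'   (\code{NA} before augmentation).
#'
#' @aliases KnnGraph-class
#' @exportClass KnnGraph
setClass("KnnGraph",
  representation(
    adjacency = "matrix",
    weightPool = "numeric",
    threshold = "numeric"
  ),
  prototype(threshold = NA_real_)
)

setValidity("KnnGraph", function(object) {
  a <- object@adjacency
  if (!is.logical(a)) return("adjacency must be a logical matrix")
  if (nrow(a) != ncol(a)) return("adjacency must be square")
  if (any(diag(a))) return("adjacency must have a zero diagonal")
  if (!identical(a, t(a))) return("adjacency must be symmetric")
  TRUE
})

#' Integer-weighted ensemble similarity network
#'
#' The ensemble network counts, for every cell pair, how many of the L
#' augmented KNN graphs contain that edge. Edges supported by fewer than
#' half of the similarity estimates are pruned as likely false positives.
#'
#' @slot weights N x N symmetric integer-valued matrix of edge support
#'   counts (0..L), zero diagonal.
#' @slot pruned same matrix with entries below L/2 set to zero.
#' @slot nSamplings number of similarity estimates L aggregated.
#'
#' @aliases EnsembleNetwork-class
#' @exportClass EnsembleNetwork
setClass("EnsembleNetwork",
  representation(
    weights = "matrix",
    pruned = "matrix",
    nSamplings = "integer"
  )
)

setValidity("EnsembleNetwork", function(object) {
  w <- object@weights
  p <- object@pruned
  L <- object@nSamplings
  if (nrow(w) != ncol(w)) return("weights must be square")
  if (!identical(dim(w), dim(p))) return("weights and pruned must share dimensions")
  if (any(diag(w) != 0) || any(diag(p) != 0)) return("diagonals must be zero")
  if (max(abs(w - t(w))) != 0) return("weights must be symmetric")
  if (any(w < 0) || any(w > L)) return("weights must lie in [0, L]")
  nz <- p[p != 0]
  if (length(nz) && any(nz < L / 2)) return("pruned nonzero weights must be >= L/2")
  TRUE
})

#' Random-walk transition matrices over the ensemble network
#'
#' Column-stochastic first-order transition probabilities over the pruned
#' ensemble network, and the second-order matrix R = P_E P_E that lets the
#' walker reach neighbours of neighbours in one step. Cells isolated after
#' pruning carry a unit self-loop so every column remains stochastic.
#'
#' @slot PE N x N column-stochastic first-order transition matrix.
#' @slot R N x N column-stochastic second-order transition matrix.
#'
#' @aliases TransitionMatrix-class
#' @exportClass TransitionMatrix
setClass("TransitionMatrix",
  representation(PE = "matrix", R = "matrix")
)

setValidity("TransitionMatrix", function(object) {
  for (nm in c("PE", "R")) {
    m <- slot(object, nm)
    if (any(m < 0)) return(paste(nm, "must be nonnegative"))
    if (max(abs(colSums(m) - 1)) > 1e-12) {
      return(paste("columns of", nm, "must sum to 1"))
    }
  }
  TRUE
})

#' Intermediate clustering state
#'
#' Per-cell integer labels together with the feature-gene expression matrix
#' used for correlation-based comparisons and the per-cluster mean expression
#' profiles (centroids) in that feature space.
#'
#' @slot labels integer vector of cluster labels in 1..nClusters, one per cell.
#' @slot featureExpr F x N matrix of normalized expression over the clustering
#'   feature genes.
#' @slot centroids F x nClusters matrix of per-cluster mean feature expression;
#'   column j is the centroid of cluster j.
#' @slot mergeTrace list of integer pairs recording the merge history
#'   (labels at time of merge).
#'
#' @aliases ClusterState-class
#' @exportClass ClusterState
setClass("ClusterState",
  representation(
    labels = "integer",
    featureExpr = "matrix",
    centroids = "matrix",
    mergeTrace = "list"
  ),
  prototype(mergeTrace = list())
)

setValidity("ClusterState", function(object) {
  k <- ncol(object@centroids)
  if (length(object@labels) != ncol(object@featureExpr)) {
    return("labels length must equal number of cells in featureExpr")
  }
  if (!all(object@labels >= 1L & object@labels <= k)) {
    return("labels must lie in 1..nClusters")
  }
  if (!all(seq_len(k) %in% object@labels)) {
    return("every cluster id must be used by at least one cell")
  }
  if (nrow(object@centroids) != nrow(object@featureExpr)) {
    return("centroids must live in the feature-gene space")
  }
  TRUE
})

#' Result of a full ensemble-network clustering run
#'
#' @slot labels integer cluster labels, one per cell, named by cell id.
#' @slot kHat estimated (or user-supplied) number of clusters.
#' @slot indexCurve named numeric vector: Rubin index per candidate q
#'   (empty when the cluster number was supplied by the user).
#' @slot cleaned M x N denoised expression matrix (RWR steady state).
#' @slot network the \linkS4class{EnsembleNetwork} used for denoising.
#' @slot transition the \linkS4class{TransitionMatrix} driving the walk.
#' @slot mergeTrace list of merges performed to reach kHat clusters.
#' @slot params list of the parameters and seed the run used.
#'
#' @aliases ScensResult-class
#' @exportClass ScensResult
setClass("ScensResult",
  representation(
    labels = "integer",
    kHat = "integer",
    indexCurve = "numeric",
    cleaned = "matrix",
    network = "EnsembleNetwork",
    transition = "TransitionMatrix",
    mergeTrace = "list",
    params = "list"
  )
)

setValidity("ScensResult", function(object) {
  if (length(object@labels) != ncol(object@cleaned)) {
    return("one label per cell is required")
  }
  if (object@kHat < 1L) return("kHat must be positive")
  TRUE
})

setMethod("show", "KnnGraph", function(object) {
  cat("KnnGraph:", nrow(object@adjacency), "cells,",
      sum(object@adjacency) / 2, "edges")
  if (!is.na(object@threshold)) {
    cat(sprintf(", augmented at threshold %.4f", object@threshold))
  }
  cat("\n")
})

setMethod("show", "EnsembleNetwork", function(object) {
  n <- nrow(object@weights)
  cat("EnsembleNetwork:", n, "cells, L =", object@nSamplings, "samplings\n")
  cat("  edges before/after pruning:",
      sum(object@weights > 0) / 2, "/", sum(object@pruned > 0) / 2, "\n")
})

setMethod("show", "TransitionMatrix", function(object) {
  cat("TransitionMatrix:", nrow(object@PE), "cells;",
      "second-order density",
      sprintf("%.3f", mean(object@R > 0)), "\n")
})

setMethod("show", "ClusterState", function(object) {
  cat("ClusterState:", length(object@labels), "cells in",
      ncol(object@centroids), "clusters; sizes:",
      paste(tabulate(object@labels), collapse = " "), "\n")
})

setMethod("show", "ScensResult", function(object) {
  cat("ScensResult:", ncol(object@cleaned), "cells,",
      nrow(object@cleaned), "genes\n")
  cat("  estimated clusters:", object@kHat, "\n")
  cat("  cluster sizes:", paste(tabulate(object@labels), collapse = " "), "\n")
})
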