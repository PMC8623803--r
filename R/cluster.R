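# Per-cluster mean expression over the feature genes; columns ordered by
# cluster id. Recomputed from scratch after every reassignment (tested
# against incremental updates).
.clusterMeans <- function(featureExpr, labels, k = max(labels)) {
  vapply(seq_len(k), function(cl) {
    rowMeans(featureExpr[, labels == cl, drop = FALSE])
  }, numeric(nrow(featureExpr)))
}

# Pearson correlation between centroid columns; constant (zero-variance)
# profiles carry no similarity evidence and are mapped to -Inf so they
# never win an argmax.
.centroidCor <- function(a, b = NULL) {
  .safeCor(a, b, undefined = -Inf)
}

#' Seed clustering by K-means over-segmentation
#'
#' Starts the clustering from a deliberately large number of small, highly
#' coherent clusters: the denoised matrix is re-normalized (CPM + log2),
#' a small feature-gene set is selected (1\% by default), the cells are
#' projected onto the leading principal components, and K-means is run
#' with \code{min(nInitClusters, N)} centres. Over-segmentation preserves
#' purity; the merge step restores the estimated cluster count.
#'
#' @param cleaned denoised genes x cells matrix.
#' @param nInitClusters number of seed clusters (default 20).
#' @param featurePct feature-gene percentage for this stage (default 1).
#' @param nPcs principal components for the K-means space (default 10).
#' @param seed seed for the K-means restarts.
#' @return a \linkS4class{ClusterState}; centroids are per-cluster mean
#'   expression over the feature genes (expression space, not PC space).
#' @export
initialKmeans <- function(cleaned, nInitClusters = 20L, featurePct = 1,
                          nPcs = 10L, seed = 1L) {
  n <- ncol(cleaned)
  if (nInitClusters < 1L) stop("nInitClusters must be >= 1")
  k <- min(nInitClusters, n)
  xn <- cpmLogNormalize(cleaned)
  feats <- selectFeatureGenes(xn, featurePct)
  scores <- .pcaScores(xn[feats, , drop = FALSE], nPcs)
  if (k == n) {
    labels <- seq_len(n)  # one cell per cluster; K-means is vacuous
  } else {
    km <- withr::with_seed(seed,
      stats::kmeans(scores, centers = k, nstart = 10L, iter.max = 100L))
    labels <- as.integer(km$cluster)
  }
  fx <- xn[feats, , drop = FALSE]
  new("ClusterState", labels = labels, featureExpr = fx,
      centroids = .clusterMeans(fx, labels, k), mergeTrace = list())
}

#' Absorb singleton clusters
#'
#' A cluster holding a single cell carries no mean-expression evidence of
#' its own, so each singleton (processed in ascending cluster id, means
#' refreshed after every move) is reassigned to the cluster whose mean
#' feature-gene expression it correlates with best. Terminates with zero
#' singletons; cluster ids are compacted to 1..K afterwards.
#'
#' @param state a \linkS4class{ClusterState}.
#' @return the state with no singleton clusters.
#' @export
absorbSingletons <- function(state) {
  labels <- state@labels
  fx <- state@featureExpr
  repeat {
    sizes <- tabulate(labels, nbins = max(labels))
    singles <- which(sizes == 1L)
    if (length(singles) == 0L) break
    if (all(sizes[sizes > 0L] == 1L)) {
      stop("no anchor cluster: every cluster is a singleton")
    }
    cl <- singles[1L]
    cell <- which(labels == cl)
    others <- setdiff(which(sizes > 0L), cl)
    means <- .clusterMeans(fx, labels)[, others, drop = FALSE]
    cors <- .centroidCor(fx[, cell, drop = FALSE], means)
    target <- others[which.max(cors)]
    labels[cell] <- target
  }
  labels <- labelsToInteger(labels)
  attr(labels, "levels") <- NULL
  new("ClusterState", labels = as.integer(labels), featureExpr = fx,
      centroids = .clusterMeans(fx, labels), mergeTrace = state@mergeTrace)
}

#' Merge clusters down to the estimated count
#'
#' Iteratively merges the pair of clusters whose mean feature-gene
#' expression profiles have the highest Pearson correlation (ties broken by
#' the lowest id pair), recomputing the merged cluster's mean after every
#' step, until exactly \code{kHat} clusters remain. Labels are compacted to
#' 1..kHat in order of first appearance; the merge history is recorded.
#'
#' @param state a \linkS4class{ClusterState} without singleton clusters.
#' @param kHat target number of clusters, \code{<= nClusters(state)}.
#' @return the merged \linkS4class{ClusterState}.
#' @export
mergeToK <- function(state, kHat) {
  labels <- state@labels
  fx <- state@featureExpr
  trace <- state@mergeTrace
  k <- max(labels)
  if (kHat > k) {
    stop(sprintf("cannot reach %d clusters from %d: raise nInitClusters",
                 kHat, k))
  }
  active <- sort(unique(labels))
  means <- .clusterMeans(fx, labels)[, active, drop = FALSE]
  while (length(active) > kHat) {
    cc <- .centroidCor(means)
    cc[lower.tri(cc, diag = TRUE)] <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)
    # ties: lowest id pair (row-major over upper triangle ordered by ids)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    a <- active[best[1L]]
    b <- active[best[2L]]
    trace[[length(trace) + 1L]] <- c(from = b, into = a)
    labels[labels == b] <- a
    active <- setdiff(active, b)
    means <- .clusterMeans(fx, labels)[, active, drop = FALSE]
  }
  labels <- labelsToInteger(labels)
  attr(labels, "levels") <- NULL
  new("ClusterState", labels = as.integer(labels), featureExpr = fx,
      centroids = .clusterMeans(fx, labels), mergeTrace = trace)
}
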