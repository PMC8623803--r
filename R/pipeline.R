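#' Run the full ensemble-network clustering pipeline
#'
#' End-to-end workflow: drop unexpressed genes, normalize (CPM + log2),
#' select potential feature genes, build the ensemble similarity network
#' from repeated random feature subsamples, form the second-order
#' transition matrix, denoise by a random walk with restart, estimate the
#' number of clusters with the Rubin index (skipped when \code{nClusters}
#' is supplied), seed clusters with K-means, absorb singletons, and merge
#' down to the estimated count. Defaults follow the method's standard
#' settings: top 5\% feature genes, K = 30 neighbours, L = 20 samplings,
#' restart weight 0.7, 10 PCs, 20 initial clusters, 1\% merge features.
#'
#' @param counts genes x cells non-negative matrix (counts or expression)
#'   with gene/cell identifiers as dimnames.
#' @param nClusters optional known cluster count; when given, the
#'   Rubin-index estimation stage is bypassed.
#' @param topFeaturePct feature-gene percentage for the network stage
#'   (default 5).
#' @param nSamplings number of similarity estimates L (default 20).
#' @param knnK neighbours per cell (default 30).
#' @param nPcs principal components throughout (default 10).
#' @param subsampleFraction fraction of the feature set per draw
#'   (default 0.5).
#' @param augmentPercentile weight-pool percentile for edge augmentation
#'   (default 10).
#' @param alpha restart-weighting coefficient of the random walk
#'   (default 0.7).
#' @param qMin,qMax search range for the cluster count (defaults 2 and 20).
#' @param nInitClusters K-means seed clusters (default 20).
#' @param featurePctCluster feature-gene percentage for the clustering
#'   stage (default 1).
#' @param seed master seed driving every random stage.
#' @param verbose print per-stage progress.
#' @return a \linkS4class{ScensResult}.
#' @examples
#' sim <- simulateCounts(nGenes = 300, nCells = 90, nClusters = 3,
#'                       markersPerCluster = 20, dropoutRate = 0.3, seed = 7)
#' fit <- runEnsembleClustering(sim$counts, nClusters = 3, nSamplings = 5,
#'                              seed = 7)
#' adjustedRandIndex(clusterLabels(fit), sim$labels)
#' @export
runEnsembleClustering <- function(counts, nClusters = NULL,
                                  topFeaturePct = 5, nSamplings = 20L,
                                  knnK = 30L, nPcs = 10L,
                                  subsampleFraction = 0.5,
                                  augmentPercentile = 10, alpha = 0.7,
                                  qMin = 2L, qMax = 20L,
                                  nInitClusters = 20L,
                                  featurePctCluster = 1, seed = 1L,
                                  verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  .checkMatrix(counts, "counts")
  counts <- filterUnexpressedGenes(counts)
  say("filtered: %d genes x %d cells (%d unexpressed genes removed)",
      nrow(counts), ncol(counts), length(attr(counts, "removedGenes")))
  x <- cpmLogNormalize(counts)
  feats <- selectFeatureGenes(x, topFeaturePct)
  say("feature genes: %d", length(feats))
  net <- buildEnsembleNetwork(x, feats, nSamplings = nSamplings, knnK = knnK,
                              nPcs = nPcs,
                              subsampleFraction = subsampleFraction,
                              augmentPercentile = augmentPercentile,
                              seed = seed)
  say("ensemble network: %d / %d edges kept after pruning",
      sum(net@pruned > 0) / 2, sum(net@weights > 0) / 2)
  trans <- toTransition(net)
  cleaned <- rwrSmooth(x, trans, alpha = alpha)
  say("denoised with alpha = %.2f", alpha)
  if (is.null(nClusters)) {
    est <- estimateNClusters(cleaned, qMin = qMin, qMax = qMax, nPcs = nPcs,
                             seed = seed)
    kHat <- est$kHat
    curve <- est$curve
    say("estimated number of clusters: %d", kHat)
  } else {
    kHat <- as.integer(nClusters)
    curve <- stats::setNames(numeric(0), character(0))
  }
  state <- initialKmeans(cleaned, nInitClusters = nInitClusters,
                         featurePct = featurePctCluster, nPcs = nPcs,
                         seed = seed)
  say("initial K-means: %d clusters", nClusters(state))
  state <- absorbSingletons(state)
  if (kHat > nClusters(state)) {
    stop(sprintf(
      "estimated %d clusters but only %d remain after singleton absorption; raise nInitClusters",
      kHat, nClusters(state)))
  }
  state <- mergeToK(state, kHat)
  say("merged to %d clusters in %d steps", kHat, length(mergeTrace(state)))
  labels <- stats::setNames(clusterLabels(state), colnames(counts))
  new("ScensResult", labels = labels, kHat = kHat, indexCurve = curve,
      cleaned = cleaned, network = net, transition = trans,
      mergeTrace = mergeTrace(state),
      params = list(topFeaturePct = topFeaturePct, nSamplings = nSamplings,
                    knnK = knnK, nPcs = nPcs,
                    subsampleFraction = subsampleFraction,
                    augmentPercentile = augmentPercentile, alpha = alpha,
                    qMin = qMin, qMax = qMax, nInitClusters = nInitClusters,
                    featurePctCluster = featurePctCluster, seed = seed,
                    suppliedK = !is.null(nClusters)))
}

#' Plain-list run report
#'
#' Serializable summary of a run: parameters, estimated cluster count,
#' cluster sizes and the merge trace. Suitable for
#' \code{jsonlite::write_json}.
#'
#' @param fit a \linkS4class{ScensResult}.
#' @return a named list.
#' @export
runReport <- function(fit) {
  list(params = fit@params,
       kHat = estimatedK(fit),
       clusterSizes = as.integer(tabulate(clusterLabels(fit))),
       indexCurve = as.list(indexCurve(fit)),
       mergeTrace = lapply(mergeTrace(fit), as.list))
}
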