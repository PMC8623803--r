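#' Accessors for scens objects
#'
#' Small accessor family for the S4 containers: cluster labels, estimated
#' cluster number, the Rubin-index curve, the denoised matrix, merge history,
#' network weight matrices and transition probabilities.
#'
#' @param object a scens S4 object.
#' @return The slot content named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("estimatedK", function(object) standardGeneric("estimatedK"))

#' @rdname accessors
#' @export
setGeneric("indexCurve", function(object) standardGeneric("indexCurve"))

#' @rdname accessors
#' @export
setGeneric("cleanedMatrix", function(object) standardGeneric("cleanedMatrix"))

#' @rdname accessors
#' @export
setGeneric("mergeTrace", function(object) standardGeneric("mergeTrace"))

#' @rdname accessors
#' @export
setGeneric("ensembleWeights", function(object) standardGeneric("ensembleWeights"))

#' @rdname accessors
#' @export
setGeneric("prunedWeights", function(object) standardGeneric("prunedWeights"))

#' @rdname accessors
#' @export
setGeneric("nSamplings", function(object) standardGeneric("nSamplings"))

#' @rdname accessors
#' @export
setGeneric("transitionProbs", function(object) standardGeneric("transitionProbs"))

#' @rdname accessors
#' @export
setGeneric("secondOrderProbs", function(object) standardGeneric("secondOrderProbs"))

#' @rdname accessors
#' @export
setGeneric("knnAdjacency", function(object) standardGeneric("knnAdjacency"))

#' @rdname accessors
#' @export
setGeneric("edgeThreshold", function(object) standardGeneric("edgeThreshold"))

#' @rdname accessors
#' @export
setGeneric("edgeWeightPool", function(object) standardGeneric("edgeWeightPool"))

#' @rdname accessors
#' @export
setGeneric("clusterCentroids", function(object) standardGeneric("clusterCentroids"))

#' @rdname accessors
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' @rdname accessors
#' @export
setMethod("knnAdjacency", "KnnGraph", function(object) object@adjacency)

#' @rdname accessors
#' @export
setMethod("edgeThreshold", "KnnGraph", function(object) object@threshold)

#' @rdname accessors
#' @export
setMethod("edgeWeightPool", "KnnGraph", function(object) object@weightPool)

#' @rdname accessors
#' @export
setMethod("ensembleWeights", "EnsembleNetwork", function(object) object@weights)

#' @rdname accessors
#' @export
setMethod("prunedWeights", "EnsembleNetwork", function(object) object@pruned)

#' @rdname accessors
#' @export
setMethod("nSamplings", "EnsembleNetwork", function(object) object@nSamplings)

#' @rdname accessors
#' @export
setMethod("transitionProbs", "TransitionMatrix", function(object) object@PE)

#' @rdname accessors
#' @export
setMethod("secondOrderProbs", "TransitionMatrix", function(object) object@R)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterState", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("clusterCentroids", "ClusterState", function(object) object@centroids)

#' @rdname accessors
#' @export
setMethod("nClusters", "ClusterState", function(object) ncol(object@centroids))

#' @rdname accessors
#' @export
setMethod("mergeTrace", "ClusterState", function(object) object@mergeTrace)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ScensResult", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("estimatedK", "ScensResult", function(object) object@kHat)

#' @rdname accessors
#' @export
setMethod("indexCurve", "ScensResult", function(object) object@indexCurve)

#' @rdname accessors
#' @export
setMethod("cleanedMatrix", "ScensResult", function(object) object@cleaned)

#' @rdname accessors
#' @export
setMethod("mergeTrace", "ScensResult", function(object) object@mergeTrace)
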