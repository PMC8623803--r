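# Cleaned matrix fixture for the clustering stage: a clear 5-cluster draw
# run through the network + smoothing stages once per file.
clusterFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- mediumSim(seed = 17)
      x <- cpmLogNormalize(sim$counts)
      f <- selectFeatureGenes(x, 5)
      net <- suppressWarnings(buildEnsembleNetwork(x, f, nSamplings = 10,
                                                   knnK = 20, seed = 17))
      cleaned <- rwrSmooth(x, toTransition(net))
      cache <<- list(sim = sim, cleaned = cleaned)
    }
    cache
  }
})

test_that("initial K-means over-segments without losing purity", {
  fx <- clusterFixture()
  st <- initialKmeans(fx$cleaned, nInitClusters = 20, featurePct = 5,
                      seed = 17)
  expect_identical(nClusters(st), 20L)
  tab <- table(clusterLabels(st), fx$sim$labels)
  purity <- sum(apply(tab, 1, max)) / ncol(fx$cleaned)
  expect_gte(purity, 0.9)
  # determinism
  st2 <- initialKmeans(fx$cleaned, nInitClusters = 20, featurePct = 5,
                       seed = 17)
  expect_identical(clusterLabels(st), clusterLabels(st2))
})

test_that("requesting one cluster per cell saturates", {
  sim <- smallSim()
  cleaned <- cpmLogNormalize(sim$counts)[, 1:25]
  st <- initialKmeans(cleaned, nInitClusters = 25, featurePct = 20, seed = 1)
  expect_identical(nClusters(st), 25L)
  expect_identical(sort(unique(clusterLabels(st))), 1:25)
})

test_that("singleton absorption follows the highest centroid correlation", {
  # state built by hand: clusters 1 and 2 have 3 cells each, cluster 3 is a
  # singleton whose profile equals cluster 2's mean exactly
  m2 <- c(1, 5, 2, 8)
  fx <- cbind(c(4, 1, 6, 0), c(5, 0, 7, 1), c(6, 2, 8, 2),
              m2 + c(-1, 1, 0, 0), m2 + c(1, -1, 0, 0), m2, m2)
  rownames(fx) <- paste0("g", 1:4)
  colnames(fx) <- paste0("c", 1:7)
  labels <- c(1L, 1L, 1L, 2L, 2L, 2L, 3L)
  st <- new("ClusterState", labels = labels, featureExpr = fx,
            centroids = vapply(1:3, function(k)
              rowMeans(fx[, labels == k, drop = FALSE]), numeric(4)))
  out <- absorbSingletons(st)
  expect_identical(nClusters(out), 2L)
  expect_identical(clusterLabels(out)[7], clusterLabels(out)[6])
  # no singletons: state passes through unchanged
  out2 <- absorbSingletons(out)
  expect_identical(clusterLabels(out2), clusterLabels(out))
  # all-singleton states have no anchor to absorb into
  stAll <- new("ClusterState", labels = 1:3, featureExpr = fx[, 1:3],
               centroids = fx[, 1:3])
  expect_error(absorbSingletons(stAll), "no anchor")
})

test_that("merging joins the most correlated centroid pair first", {
  # clusters 1 and 2 share a mean profile (correlation 1); 3 differs
  fx <- cbind(c(1, 2, 3), c(1, 2, 3), c(2, 4, 6), c(2, 4, 6),
              c(9, 1, 4), c(9, 1, 4))
  rownames(fx) <- paste0("g", 1:3)
  colnames(fx) <- paste0("c", 1:6)
  labels <- rep(1:3, each = 2L)
  st <- new("ClusterState", labels = labels, featureExpr = fx,
            centroids = vapply(1:3, function(k)
              rowMeans(fx[, labels == k, drop = FALSE]), numeric(3)))
  out <- mergeToK(st, 2)
  expect_identical(nClusters(out), 2L)
  expect_identical(clusterLabels(out)[1], clusterLabels(out)[3])
  expect_length(mergeTrace(out), 1L)
  # kHat equal to the current count is the identity
  same <- mergeToK(st, 3)
  expect_identical(clusterLabels(same), labels)
  # more clusters than exist cannot be requested
  expect_error(mergeToK(st, 5), "raise nInitClusters")
})

test_that("merging is a pure coarsening that recovers planted clusters", {
  fx <- clusterFixture()
  st <- initialKmeans(fx$cleaned, nInitClusters = 20, featurePct = 5,
                      seed = 17)
  st2 <- absorbSingletons(st)
  out <- mergeToK(st2, 5)
  expect_identical(nClusters(out), 5L)
  expect_identical(length(mergeTrace(out)),
                   nClusters(st2) - 5L)
  # coarsening: cells sharing a post-absorption cluster still share one
  agree <- tapply(clusterLabels(out), clusterLabels(st2),
                  function(v) length(unique(v)))
  expect_true(all(agree == 1))
  expect_gte(adjustedRandIndex(clusterLabels(out), fx$sim$labels), 0.9)
})

test_that("cluster means always equal direct recomputation", {
  fx <- clusterFixture()
  st <- initialKmeans(fx$cleaned, nInitClusters = 15, featurePct = 5,
                      seed = 3)
  for (s in list(st, absorbSingletons(st),
                 mergeToK(absorbSingletons(st), 6))) {
    direct <- vapply(seq_len(nClusters(s)), function(k)
      rowMeans(s@featureExpr[, clusterLabels(s) == k, drop = FALSE]),
      numeric(nrow(s@featureExpr)))
    expect_equal(unname(clusterCentroids(s)), unname(direct),
                 tolerance = 1e-12)
  }
})
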