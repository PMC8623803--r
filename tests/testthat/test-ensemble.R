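test_that("feature subsampling is deterministic and uniform", {
  f <- 1:100
  expect_identical(sampleFeatureSubset(f, 1.0, seed = 3), f)  # identity
  expect_identical(sampleFeatureSubset(f, 0.5, seed = 9),
                   sampleFeatureSubset(f, 0.5, seed = 9))
  expect_length(sampleFeatureSubset(f, 0.5, seed = 1), 50)
  # tiny fractions are floored at two genes
  expect_length(sampleFeatureSubset(f, 0.001, seed = 1), 2)
  # Monte-Carlo uniformity: inclusion frequency ~ Binomial(n, 0.5)
  nDraw <- 10000
  counts <- integer(10)
  for (i in seq_len(nDraw)) {
    idx <- sampleFeatureSubset(1:10, 0.5, seed = i)
    counts[idx] <- counts[idx] + 1L
  }
  sigma <- sqrt(nDraw * 0.5 * 0.5)
  expect_true(all(abs(counts - nDraw * 0.5) <= 3 * sigma))
})

test_that("PC-score similarity matches a hand eigendecomposition", {
  x <- rbind(g1 = c(1, 2, 4), g2 = c(2, 1, 0))
  colnames(x) <- paste0("c", 1:3)
  s <- estimateSimilarity(x, 1:2, nPcs = 2)
  # oracle: centre cells (columns as 2-vectors), eigen of covariance,
  # correlate score vectors directly
  y <- t(x)
  y <- sweep(y, 2, colMeans(y))
  ev <- eigen(crossprod(y) / (nrow(y) - 1))
  sc <- y %*% ev$vectors
  oracle <- suppressWarnings(stats::cor(t(sc)))
  expect_equal(abs(s), abs(oracle), tolerance = 1e-12, ignore_attr = TRUE)
  # identical cells over the subset correlate at exactly 1
  x2 <- rbind(g1 = c(1, 1, 5), g2 = c(3, 3, 0), g3 = c(2, 2, 9))
  colnames(x2) <- paste0("c", 1:3)
  s2 <- estimateSimilarity(x2, 1:3, nPcs = 2)
  expect_equal(s2[1, 2], 1)
})

test_that("similarity is equivariant under cell permutation", {
  sim <- smallSim()
  x <- cpmLogNormalize(sim$counts)
  f <- selectFeatureGenes(x, 10)
  s <- estimateSimilarity(x, f, 10)
  p <- sample(ncol(x))
  sp <- estimateSimilarity(x[, p], f, 10)
  expect_equal(sp, s[p, p], tolerance = 1e-9)
  expect_equal(s, t(s))
  expect_equal(unname(diag(s)), rep(1, ncol(x)))
})

test_that("KNN construction takes the k strongest neighbours, union-undirected", {
  s <- matrix(c(1, .9, .2, .9, 1, .5, .2, .5, 1), 3, 3)
  g <- buildKnnGraph(s, k = 1)
  expect_identical(unname(knnAdjacency(g)),
                   matrix(c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
                            FALSE, TRUE, FALSE), 3))
  expect_setequal(edgeWeightPool(g), c(.9, .5))
  # k = N-1 saturates to the complete graph
  gc <- buildKnnGraph(s, k = 2)
  expect_true(all(knnAdjacency(gc)[upper.tri(s)]))
  # ties at the k-th rank resolve to the lower cell index: with all
  # correlations equal, every cell picks its lowest-index peer, so the
  # union is the star on cell 1 plus the 1-2 edge
  st <- matrix(0.5, 4, 4); diag(st) <- 1
  gt <- buildKnnGraph(st, k = 1)
  expect_identical(unname(gt@adjacency),
                   rbind(c(FALSE, TRUE, TRUE, TRUE),
                         c(TRUE, FALSE, FALSE, FALSE),
                         c(TRUE, FALSE, FALSE, FALSE),
                         c(TRUE, FALSE, FALSE, FALSE)))
})

test_that("augmentation adds above-threshold edges on top of the KNN floor", {
  s <- matrix(c(1, .9, .2, .9, 1, .5, .2, .5, 1), 3, 3)
  g <- buildKnnGraph(s, k = 1)
  ga <- augmentGraph(g, s, percentile = 10)
  expect_equal(edgeThreshold(ga),
               as.numeric(quantile(c(.5, .9), 0.1)))
  # KNN edges 1-2 and 2-3 are retained; 1-3 (0.2) stays out
  expect_true(ga@adjacency[1, 2] && ga@adjacency[2, 3])
  expect_false(ga@adjacency[1, 3])
  # percentile 100: no correlation strictly exceeds the max, so the
  # augmented graph equals the KNN graph
  g100 <- augmentGraph(g, s, percentile = 100)
  expect_identical(g100@adjacency, knnAdjacency(g))
  # equal correlations: nothing strictly exceeds the threshold either
  se <- matrix(0.5, 4, 4); diag(se) <- 1
  ge <- buildKnnGraph(se, k = 2)
  expect_identical(augmentGraph(ge, se, 10)@adjacency, knnAdjacency(ge))
})

test_that("ensemble aggregation counts support and prunes below L/2", {
  a1 <- matrix(FALSE, 3, 3); a1[1, 2] <- a1[2, 1] <- TRUE
  a2 <- a1; a3 <- a1
  a3[2, 3] <- a3[3, 2] <- TRUE  # edge 2-3 appears once out of L=3
  gs <- lapply(list(a1, a2, a3), function(a)
    new("KnnGraph", adjacency = a, weightPool = 0.5, threshold = NA_real_))
  expect_warning(net <- aggregateEnsemble(gs), "isolated")
  expect_equal(ensembleWeights(net)[1, 2], 3)
  expect_equal(ensembleWeights(net)[2, 3], 1)
  expect_equal(prunedWeights(net)[1, 2], 3)  # 3 >= 1.5 kept
  expect_equal(prunedWeights(net)[2, 3], 0)  # 1 < 1.5 pruned
  # L = 1: every edge has weight 1 >= 0.5, nothing is pruned
  n1 <- suppressWarnings(aggregateEnsemble(gs[1]))
  expect_equal(prunedWeights(n1), ensembleWeights(n1))
  # identical graphs scale linearly and a weight of exactly L/2 is kept
  a4 <- a3
  gs2 <- list(gs[[3]], gs[[3]], gs[[1]], gs[[1]])
  net2 <- aggregateEnsemble(gs2)
  expect_equal(ensembleWeights(net2)[2, 3], 2)
  expect_equal(prunedWeights(net2)[2, 3], 2)  # 2 == L/2 survives
})

test_that("transition matrices are column-stochastic with second-order reach", {
  a <- matrix(c(0, 2, 2, 0), 2, 2)
  net <- new("EnsembleNetwork", weights = a, pruned = a, nSamplings = 2L)
  tr <- toTransition(net)
  expect_equal(transitionProbs(tr), matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(secondOrderProbs(tr), diag(2))
  # star with centre 1: leaves reach each other in two hops
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 3
  netS <- new("EnsembleNetwork", weights = star, pruned = star,
              nSamplings = 3L)
  r <- secondOrderProbs(toTransition(netS))
  expect_true(all(r[2:4, 2:4] > 0))
  expect_equal(unname(colSums(r)), rep(1, 4), tolerance = 1e-12)
})

test_that("network matrices stay symmetric with zero diagonals at every stage", {
  sim <- smallSim()
  x <- cpmLogNormalize(sim$counts)
  f <- selectFeatureGenes(x, 10)
  for (l in 1:3) {
    fl <- sampleFeatureSubset(f, 0.5, seed = l)
    s <- estimateSimilarity(x, fl, 10)
    g <- augmentGraph(buildKnnGraph(s, 10), s, 10)
    expect_identical(g@adjacency, t(g@adjacency))
    expect_false(any(diag(g@adjacency)))
  }
  net <- suppressWarnings(buildEnsembleNetwork(x, f, nSamplings = 5,
                                               knnK = 10, seed = 4))
  w <- ensembleWeights(net); p <- prunedWeights(net)
  expect_identical(w, t(w))
  expect_identical(p, t(p))
  expect_true(all(diag(w) == 0) && all(diag(p) == 0))
  expect_true(all(p[p != 0] >= nSamplings(net) / 2))
  tr <- toTransition(net)
  expect_equal(unname(colSums(transitionProbs(tr))), rep(1, ncol(x)),
               tolerance = 1e-12)
  expect_equal(unname(colSums(secondOrderProbs(tr))), rep(1, ncol(x)),
               tolerance = 1e-12)
})

test_that("a single full-fraction sampling reduces to one augmented KNN graph", {
  sim <- smallSim()
  x <- cpmLogNormalize(sim$counts)
  f <- selectFeatureGenes(x, 10)
  net <- buildEnsembleNetwork(x, f, nSamplings = 1, knnK = 10,
                              subsampleFraction = 1.0, seed = 5)
  # independent straightforward implementation on the same similarity
  s <- estimateSimilarity(x, f, 10)
  ref <- naiveAugmentedKnn(s, k = 10, percentile = 10)
  expect_identical(unname(ensembleWeights(net) > 0), unname(ref))
  expect_identical(ensembleWeights(net), prunedWeights(net))
})
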