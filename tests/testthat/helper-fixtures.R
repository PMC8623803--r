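# Shared fixtures and independent oracles. Fixtures are generated in code;
# the "small" draw keeps unit tests fast, the clustering tests use a
# moderately sized draw with clear structure.

smallSim <- function(seed = 11, dropoutRate = 0.3) {
  simulateCounts(nGenes = 300, nCells = 90, nClusters = 3,
                 markersPerCluster = 20, markerLogFold = 3,
                 dropoutRate = dropoutRate, seed = seed)
}

mediumSim <- function(seed = 11, dropoutRate = 0.4, nClusters = 5) {
  simulateCounts(nGenes = 1000, nCells = 250, nClusters = nClusters,
                 markersPerCluster = 40, markerLogFold = 2.5,
                 dropoutRate = dropoutRate, seed = seed)
}

# Brute-force pair-counting metrics by explicit enumeration of all
# unordered pairs; independent of the contingency-table implementations.
bruteForcePairs <- function(p, c) {
  n <- length(p)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      sp <- p[i] == p[j]
      sc <- c[i] == c[j]
      if (sp && sc) tp <- tp + 1
      else if (sp && !sc) fp <- fp + 1
      else if (!sp && sc) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

bruteForceJaccard <- function(p, c) {
  pc <- bruteForcePairs(p, c)
  pc[["TP"]] / (pc[["TP"]] + pc[["FP"]] + pc[["FN"]])
}

bruteForceARI <- function(p, c) {
  pc <- bruteForcePairs(p, c)
  n <- length(p)
  total <- n * (n - 1) / 2
  a <- pc[["TP"]] + pc[["FP"]]
  b <- pc[["TP"]] + pc[["FN"]]
  expected <- a * b / total
  maxIdx <- (a + b) / 2
  (pc[["TP"]] - expected) / (maxIdx - expected)
}

# Full joint-table mutual information / entropies, written directly from
# the definitions with explicit loops.
bruteForceNMI <- function(p, c) {
  n <- length(p)
  pu <- unique(p)
  cu <- unique(c)
  hp <- 0
  for (a in pu) { q <- mean(p == a); hp <- hp - q * log(q) }
  hc <- 0
  for (b in cu) { q <- mean(c == b); hc <- hc - q * log(q) }
  mi <- 0
  for (a in pu) {
    for (b in cu) {
      pj <- mean(p == a & c == b)
      if (pj > 0) mi <- mi + pj * log(pj / (mean(p == a) * mean(c == b)))
    }
  }
  if (hp + hc == 0) return(1)
  2 * mi / (hp + hc)
}

# Straightforward single-graph reference: KNN by sorting, percentile
# threshold, union augmentation — written independently of the package
# internals (explicit loops, no shared helpers).
naiveAugmentedKnn <- function(sim, k, percentile = 10) {
  n <- nrow(sim)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- setdiff(order(sim[i, ], decreasing = TRUE), i)
    adj[i, ord[seq_len(k)]] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  pool <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (adj[i, j]) pool <- c(pool, sim[i, j])
    }
  }
  eth <- as.numeric(stats::quantile(pool, percentile / 100))
  out <- adj
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && sim[i, j] > eth) out[i, j] <- TRUE
    }
  }
  out
}
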