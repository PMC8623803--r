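#' Draw a random subset of the feature genes
#'
#' Uniform sampling without replacement of \code{round(fraction * |F|)}
#' genes (at least 2) from the potential feature-gene set. Each gene has
#' equal inclusion probability; the draw is deterministic given the seed.
#'
#' @param features integer vector of feature-gene row indices.
#' @param fraction proportion of features per draw, in (0, 1].
#' @param seed integer seed for this draw.
#' @return sorted integer vector of sampled indices.
#' @export
sampleFeatureSubset <- function(features, fraction = 0.5, seed = 1L) {
  if (length(features) < 2L) stop("need at least 2 feature genes")
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  n <- max(2L, round(fraction * length(features)))
  n <- min(n, length(features))
  withr::with_seed(seed, sort(sample(features, n)))
}

#' Cell-cell similarity from PCA scores
#'
#' Restricts the normalized matrix to a feature subset, projects the cells
#' onto the leading principal components (cells are the observations, genes
#' the mean-centred variables) and returns the Pearson correlation between
#' the cells' PC score vectors.
#'
#' @param x normalized genes x cells matrix.
#' @param subset integer row indices (a feature-gene subset).
#' @param nPcs number of principal components (default 10).
#' @return N x N symmetric correlation matrix with unit diagonal; a cell
#'   with zero variance across its scores gets zero correlations (with a
#'   warning).
#' @export
estimateSimilarity <- function(x, subset, nPcs = 10L) {
  if (nPcs < 1L) stop("nPcs must be >= 1")
  if (nPcs > min(length(subset), ncol(x))) {
    stop("nPcs exceeds min(|subset|, number of cells)")
  }
  scores <- .pcaScores(x[subset, , drop = FALSE], nPcs)
  flat <- apply(scores, 1L, stats::sd) == 0
  cc <- .safeCor(t(scores), undefined = 0)
  if (any(flat)) {
    warning(sum(flat), " cell(s) with zero variance across PC scores; ",
            "their correlations are set to 0")
    cc[flat, ] <- 0
    cc[, flat] <- 0
  }
  diag(cc) <- 1
  dimnames(cc) <- list(colnames(x), colnames(x))
  cc
}

#' Build a K-nearest-neighbour graph from a similarity matrix
#'
#' Connects every cell to its \code{k} most similar cells (self excluded);
#' edges are undirected (union of both directions). Ties at the k-th rank
#' are broken by lower cell index. The multiset of Pearson correlations on
#' the resulting edges is retained as the weight pool used later to set the
#' augmentation threshold (each undirected edge contributes once).
#'
#' @param sim N x N symmetric similarity matrix.
#' @param k number of neighbours, in 1..N-1.
#' @return a \linkS4class{KnnGraph}.
#' @export
buildKnnGraph <- function(sim, k = 30L) {
  n <- ncol(sim)
  if (k < 1L || k > n - 1L) stop("k must be in 1..N-1")
  adj <- matrix(FALSE, n, n, dimnames = dimnames(sim))
  for (i in seq_len(n)) {
    cand <- sim[i, ]
    cand[i] <- -Inf
    # stable radix order on the negated values: ties at the k-th rank
    # resolve to the lower cell index
    nb <- order(-cand, method = "radix")[seq_len(k)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  pool <- sim[upper.tri(sim) & adj]
  new("KnnGraph", adjacency = adj, weightPool = pool, threshold = NA_real_)
}

#' Augment a KNN graph by a correlation threshold
#'
#' Sets the threshold to the given percentile (linear interpolation between
#' order statistics) of the KNN edge weight pool, then adds an edge between
#' every cell pair whose correlation is strictly greater than the
#' threshold. KNN edges are retained: a K-nearest-neighbour list is the
#' method's floor on connectivity, and augmentation only densifies
#' within-type cliques beyond it. Cells whose K neighbours are weakly and
#' inconsistently correlated would otherwise be disconnected by the later
#' ensemble pruning and re-enter the walk as unsmoothed outliers.
#'
#' @param g a \linkS4class{KnnGraph} built from \code{sim}.
#' @param sim the similarity matrix the graph was built from.
#' @param percentile percentile of the weight pool used as threshold
#'   (default 10).
#' @return the augmented \linkS4class{KnnGraph} with \code{edgeThreshold}
#'   set.
#' @export
augmentGraph <- function(g, sim, percentile = 10) {
  eth <- stats::quantile(g@weightPool, percentile / 100, names = FALSE,
                         type = 7L)
  adj <- g@adjacency | sim > eth
  diag(adj) <- FALSE
  new("KnnGraph", adjacency = adj, weightPool = g@weightPool,
      threshold = eth)
}

#' Aggregate augmented KNN graphs into the ensemble network
#'
#' Sums the L binary adjacency matrices into an integer-weighted edge
#' support count, then prunes edges supported by fewer than half of the
#' similarity estimates (weight < L/2; a weight of exactly L/2 is kept).
#'
#' @param graphs list of \linkS4class{KnnGraph} objects over the same cells.
#' @return an \linkS4class{EnsembleNetwork}; warns if pruning isolates a
#'   cell (it will then keep only its own signal under the random walk).
#' @export
aggregateEnsemble <- function(graphs) {
  if (length(graphs) < 1L) stop("need at least one graph")
  L <- length(graphs)
  w <- Reduce(`+`, lapply(graphs, function(g) g@adjacency * 1))
  pruned <- w
  pruned[pruned < L / 2] <- 0
  iso <- colSums(pruned) == 0
  if (any(iso)) {
    warning(sum(iso), " cell(s) isolated after pruning; they keep only ",
            "their own signal under the random walk")
  }
  new("EnsembleNetwork", weights = w, pruned = pruned,
      nSamplings = as.integer(L))
}

#' Transition matrices of the random walker
#'
#' Degree-normalizes the pruned ensemble network into a column-stochastic
#' first-order transition matrix P_E and forms the second-order matrix
#' R = P_E P_E, which lets the walker reach neighbours of neighbours while
#' avoiding the false edges denser higher orders would introduce.
#'
#' A cell isolated by pruning would keep its raw, unsmoothed profile and
#' re-enter the denoised matrix as an extreme outlier, distorting the
#' variance-based feature selection of the later stages. Such cells are
#' instead connected to the neighbours with the highest support in the
#' unpruned ensemble (their strongest evidence, even if below the pruning
#' threshold); a unit self-loop remains the fallback for a cell with no
#' ensemble edges at all.
#'
#' @param e an \linkS4class{EnsembleNetwork}.
#' @return a \linkS4class{TransitionMatrix}.
#' @export
toTransition <- function(e) {
  a <- e@pruned
  iso <- colSums(a) == 0
  for (j in which(iso)) {
    w <- e@weights[, j]
    if (max(w) > 0) {
      nb <- which(w == max(w))
      a[nb, j] <- w[nb]
      a[j, nb] <- w[nb]
    } else {
      a[j, j] <- 1
    }
  }
  cs <- colSums(a)
  pe <- sweep(a, 2L, cs, "/")
  new("TransitionMatrix", PE = pe, R = pe %*% pe)
}

#' Build the full ensemble similarity network
#'
#' Runs L rounds of feature subsampling, PCA + Pearson similarity, KNN
#' construction and threshold augmentation, then aggregates and prunes.
#' Draw l uses seed + l, so draws are independent yet reproducible from one
#' master seed.
#'
#' @param x normalized genes x cells matrix.
#' @param features feature-gene row indices (see
#'   \code{\link{selectFeatureGenes}}).
#' @param nSamplings number of similarity estimates L (default 20).
#' @param knnK neighbours per cell (default 30, capped at N-1).
#' @param nPcs principal components per estimate (default 10).
#' @param subsampleFraction fraction of features per draw (default 0.5).
#' @param augmentPercentile weight-pool percentile for the augmentation
#'   threshold (default 10).
#' @param seed master seed.
#' @return an \linkS4class{EnsembleNetwork}.
#' @export
buildEnsembleNetwork <- function(x, features, nSamplings = 20L, knnK = 30L,
                                 nPcs = 10L, subsampleFraction = 0.5,
                                 augmentPercentile = 10, seed = 1L) {
  k <- min(knnK, ncol(x) - 1L)
  graphs <- lapply(seq_len(nSamplings), function(l) {
    fl <- sampleFeatureSubset(features, subsampleFraction, seed + l)
    sim <- estimateSimilarity(x, fl, min(nPcs, length(fl)))
    g <- buildKnnGraph(sim, k)
    augmentGraph(g, sim, augmentPercentile)
  })
  aggregateEnsemble(graphs)
}
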