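#' Rubin index of a clustering
#'
#' Ratio det(T) / det(W) of the total scatter matrix about the grand mean
#' to the pooled within-cluster scatter matrix. Larger values indicate
#' tighter clusters; with a single cluster the index is 1 by construction,
#' and it is invariant to rigid rotations of the points. For 1-D data the
#' determinants reduce to sums of squares. Computed through log
#' determinants for numerical range.
#'
#' @param points N x d matrix of observations (rows).
#' @param labels integer or factor cluster labels, one per row.
#' @return the Rubin index (positive scalar).
#' @examples
#' rubinIndex(cbind(c(0, 1, 10, 11)), c(1, 1, 2, 2))  # 101
#' @export
rubinIndex <- function(points, labels) {
  points <- as.matrix(points)
  if (nrow(points) != length(labels)) stop("one label per point is required")
  tot <- crossprod(sweep(points, 2L, colMeans(points), "-"))
  w <- matrix(0, ncol(points), ncol(points))
  for (cl in unique(labels)) {
    p <- points[labels == cl, , drop = FALSE]
    w <- w + crossprod(sweep(p, 2L, colMeans(p), "-"))
  }
  ldW <- determinant(w, logarithm = TRUE)
  if (!is.finite(ldW$modulus) || ldW$sign <= 0) {
    stop("degenerate within-scatter: singular pooled within-cluster matrix")
  }
  ldT <- determinant(tot, logarithm = TRUE)
  exp(as.numeric(ldT$modulus - ldW$modulus))
}

#' Estimate the number of clusters from a denoised matrix
#'
#' Re-normalizes the denoised data (the random walk changes per-cell
#' totals, so CPM + log2 is applied again), selects feature genes, projects
#' the cells onto the leading principal components, runs K-means for every
#' candidate cluster count q, and evaluates the Rubin index. The selected
#' count minimizes the second difference of the index curve,
#' \code{(R(q+1) - R(q)) - (R(q) - R(q-1))}, evaluated on the log scale:
#' the index is a determinant ratio that grows multiplicatively with q in
#' d dimensions, so the bend where real structure is exhausted is additive
#' in log(R). The index rises sharply until the cluster structure is
#' resolved and flattens after; the strongest negative log-scale bend marks
#' the cluster number.
#'
#' @param cleaned denoised genes x cells matrix (see
#'   \code{\link{rwrSmooth}}).
#' @param qMin,qMax inclusive search range for the cluster count; needs
#'   \code{qMax - qMin >= 2} so a second difference exists.
#' @param nPcs number of principal components (default 10).
#' @param featurePct feature-gene percentage for this stage (default 5).
#' @param seed master seed; the K-means run for candidate q uses
#'   \code{seed + q} with 10 random restarts.
#' @return list with \code{kHat} (integer) and \code{curve} (named numeric
#'   vector of Rubin index values over the searched q).
#' @export
estimateNClusters <- function(cleaned, qMin = 2L, qMax = 20L, nPcs = 10L,
                              featurePct = 5, seed = 1L) {
  n <- ncol(cleaned)
  if (qMin < 2L || qMax > n - 1L || qMin >= qMax) {
    stop("need 2 <= qMin < qMax <= N-1")
  }
  if (qMax - qMin < 2L) {
    stop("qMax - qMin must be >= 2: the second difference needs 3 consecutive q")
  }
  xn <- cpmLogNormalize(cleaned)
  feats <- selectFeatureGenes(xn, featurePct)
  scores <- .pcaScores(xn[feats, , drop = FALSE], nPcs)
  qs <- seq.int(qMin, qMax)
  curve <- numeric(length(qs))
  prev <- NULL
  for (i in seq_along(qs)) {
    q <- qs[i]
    km <- withr::with_seed(seed + q,
      stats::kmeans(scores, centers = q, nstart = 10L, iter.max = 100L))
    # deterministic warm start: split the widest cluster of the previous
    # solution; a local optimum at one q would otherwise dent the index
    # curve and fake a bend
    if (!is.null(prev)) {
      wss <- prev$withinss
      sizes <- tabulate(prev$cluster, nbins = q - 1L)
      wss[sizes < 3L] <- -Inf
      wide <- which.max(wss)
      if (is.finite(wss[wide])) {
        pts <- scores[prev$cluster == wide, , drop = FALSE]
        sub <- withr::with_seed(seed + q,
          stats::kmeans(pts, centers = 2L, nstart = 5L, iter.max = 50L))
        cents <- rbind(prev$centers[-wide, , drop = FALSE], sub$centers)
        km2 <- tryCatch(
          stats::kmeans(scores, centers = cents, iter.max = 100L),
          error = function(e) NULL)
        if (!is.null(km2) && km2$tot.withinss < km$tot.withinss) km <- km2
      }
    }
    prev <- km
    curve[i] <- tryCatch(rubinIndex(scores, km$cluster),
                         error = function(e) NA_real_)
  }
  inner <- seq.int(2L, length(qs) - 1L)
  lc <- log(curve)
  d2 <- lc[inner + 1L] - 2 * lc[inner] + lc[inner - 1L]
  if (all(!is.finite(d2))) stop("Rubin index failed for every candidate q")
  kHat <- qs[inner[which.min(d2)]]
  list(kHat = as.integer(kHat), curve = stats::setNames(curve, qs))
}
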