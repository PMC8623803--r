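# Two-sided Wilcoxon rank-sum p-values, one gene per row, group vs rest.
# Large-sample normal approximation with tie correction, no continuity
# correction (matches wilcox.test(exact = FALSE, correct = FALSE)).
.rankSumP <- function(x, inGroup) {
  n <- ncol(x)
  n1 <- sum(inGroup)
  n2 <- n - n1
  ranks <- t(apply(x, 1L, rank))
  ties <- apply(x, 1L, function(row) {
    tt <- tabulate(match(row, unique(row)))
    sum(tt^3 - tt)
  })
  w <- rowSums(ranks[, inGroup, drop = FALSE]) - n1 * (n1 + 1) / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - ties / (n * (n - 1)))
  z <- (w - n1 * n2 / 2) / sqrt(pmax(sigma2, .Machine$double.eps))
  pval <- 2 * stats::pnorm(-abs(z))
  pval[sigma2 == 0] <- 1                   # constant gene: no evidence
  pmin(pval, 1)
}

# Pair-counting confusion for two labelings: TP pairs co-clustered in both,
# FP co-clustered only in p, FN co-clustered only in c, TN in neither.
# Computed from the contingency table; TP+FP+FN+TN = choose(N, 2).
.pairConfusion <- function(p, c) {
  if (length(p) != length(c)) stop("label vectors differ in length")
  tab <- table(p, c)
  choose2 <- function(x) x * (x - 1) / 2
  tp <- sum(choose2(tab))
  fp <- sum(choose2(rowSums(tab))) - tp
  fn <- sum(choose2(colSums(tab))) - tp
  tn <- choose2(length(p)) - tp - fp - fn
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Pair-counting Jaccard index between two labelings
#'
#' TP / (TP + FP + FN) over all unordered cell pairs, where TP counts pairs
#' co-clustered in both labelings, FP pairs co-clustered only in the
#' prediction, FN pairs co-clustered only in the reference. Equals 1 on
#' identical labelings and is invariant to label permutation.
#'
#' @param p,c label vectors of equal length (any atomic type).
#' @return the Jaccard index in [0, 1].
#' @examples
#' jaccardIndex(c(1, 1, 1, 2), c(1, 1, 2, 2))  # 0.25
#' @export
jaccardIndex <- function(p, c) {
  pc <- .pairConfusion(p, c)
  denom <- pc[["TP"]] + pc[["FP"]] + pc[["FN"]]
  if (denom == 0) return(1)  # both labelings all-singletons
  pc[["TP"]] / denom
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting Rand index corrected for chance agreement under the
#' hypergeometric model of random labelings with fixed margins.
#'
#' @inheritParams jaccardIndex
#' @return the ARI (1 for identical labelings, ~0 for independent ones).
#' @export
adjustedRandIndex <- function(p, c) {
  if (length(p) != length(c)) stop("label vectors differ in length")
  tab <- table(p, c)
  choose2 <- function(x) x * (x - 1) / 2
  sumIj <- sum(choose2(tab))
  sumA <- sum(choose2(rowSums(tab)))
  sumB <- sum(choose2(colSums(tab)))
  expected <- sumA * sumB / choose2(length(p))
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) return(1)  # both labelings trivial
  (sumIj - expected) / (maxIdx - expected)
}

#' Normalized mutual information between two labelings
#'
#' 2 I(P, C) / (H(P) + H(C)) with natural-log entropies over label
#' frequencies (the base cancels in the ratio). When both labelings are
#' single-cluster (zero total entropy) the agreement is perfect and 1 is
#' returned.
#'
#' @inheritParams jaccardIndex
#' @return the NMI in [0, 1].
#' @export
normalizedMutualInformation <- function(p, c) {
  if (length(p) != length(c)) stop("label vectors differ in length")
  n <- length(p)
  joint <- table(p, c) / n
  pr <- rowSums(joint)
  pcol <- colSums(joint)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hp <- ent(pr)
  hc <- ent(pcol)
  if (hp + hc == 0) return(1)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(pr, pcol)[nz]))
  2 * mi / (hp + hc)
}

#' Recall, precision and F-score between two gene sets
#'
#' Agreement of a predicted gene set (e.g., DEGs called from predicted
#' cluster labels) with a reference set (DEGs from true labels):
#' recall = TP/(TP+FN), precision = TP/(TP+FP), F = 2PR/(P+R). An empty
#' predicted set makes precision undefined and is reported as 0 with a
#' warning; two empty sets agree perfectly (all three 1).
#'
#' @param trueSet,predictedSet vectors of gene identifiers.
#' @return named numeric vector \code{c(recall, precision, f_score)}.
#' @export
geneSetPRF <- function(trueSet, predictedSet) {
  trueSet <- unique(trueSet)
  predictedSet <- unique(predictedSet)
  if (length(trueSet) == 0L && length(predictedSet) == 0L) {
    return(c(recall = 1, precision = 1, f_score = 1))
  }
  tp <- length(intersect(trueSet, predictedSet))
  fn <- length(setdiff(trueSet, predictedSet))
  fp <- length(setdiff(predictedSet, trueSet))
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  if (length(predictedSet) == 0L) {
    warning("empty predicted set: precision undefined, reported as 0")
    precision <- 0
  } else {
    precision <- tp / (tp + fp)
  }
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(recall = recall, precision = precision, f_score = f)
}

#' Mean absolute expression error over a gene set
#'
#' Normalized disagreement between two expression matrices restricted to a
#' set of genes D: \code{sum_{i in D} sum_j |x_ij - xhat_ij| / (N * |D|)}.
#'
#' @param ref,alt matrices of identical shape (genes x cells).
#' @param degRows non-empty integer vector of row indices (the gene set D).
#' @return the normalized error (>= 0).
#' @export
normalizedExpressionError <- function(ref, alt, degRows) {
  if (!identical(dim(ref), dim(alt))) stop("matrices differ in shape")
  if (length(degRows) == 0L) stop("degRows must be non-empty")
  sum(abs(ref[degRows, , drop = FALSE] - alt[degRows, , drop = FALSE])) /
    (ncol(ref) * length(degRows))
}

#' Rank-sum one-vs-rest differential expression caller
#'
#' For each cluster, tests every gene with a two-sided Wilcoxon rank-sum
#' test (cluster vs all other cells; large-sample normal approximation with
#' tie correction, vectorised over genes) and keeps genes with
#' \code{p < pThresh} whose fold change exceeds \code{fcThresh}. The fold
#' change is the ratio of mean expression on the un-logged scale
#' (\code{2^x - 1}), cluster vs rest. Intended to exercise the gene-set
#' agreement metrics end to end; it is not a model-based DE method.
#'
#' @param x normalized (log2 scale) genes x cells matrix.
#' @param labels cluster labels, one per cell.
#' @param pThresh p-value threshold (default 0.05).
#' @param fcThresh fold-change threshold (default 1.5).
#' @return named list, one character vector of gene ids per cluster;
#'   clusters of size 1 are excluded with a warning.
#' @export
simpleDegCaller <- function(x, labels, pThresh = 0.05, fcThresh = 1.5) {
  labels <- labelsToInteger(labels)
  k <- max(labels)
  if (k < 2L) stop("need at least 2 clusters")
  n <- ncol(x)
  lin <- 2^x - 1                           # un-logged scale for fold change
  out <- list()
  for (cl in seq_len(k)) {
    inCl <- labels == cl
    n1 <- sum(inCl)
    if (n1 < 2L) {
      warning("cluster ", cl, " has a single cell; excluded from DE calling")
      next
    }
    pval <- .rankSumP(x, inCl)
    meanIn <- rowMeans(lin[, inCl, drop = FALSE])
    meanOut <- rowMeans(lin[, !inCl, drop = FALSE])
    fc <- meanIn / pmax(meanOut, .Machine$double.eps)
    hit <- pval < pThresh & fc > fcThresh
    out[[as.character(cl)]] <- rownames(x)[hit] %||% which(hit)
  }
  out
}
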