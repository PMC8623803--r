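# Internal helpers shared across modules.

# PCA scores for cells. x is genes x cells; cells are the observations,
# genes the variables; variables are mean-centred but not scaled. Returns
# a cells x nPcs score matrix with a deterministic sign convention: the
# loading with the largest magnitude on each component is made positive
# (first index wins on ties).
.pcaScores <- function(x, nPcs) {
  xt <- t(x)
  xt <- sweep(xt, 2L, colMeans(xt), "-")
  nPcs <- min(nPcs, nrow(xt), ncol(xt))
  sv <- svd(xt, nu = 0L, nv = nPcs)
  v <- sv$v[, seq_len(nPcs), drop = FALSE]
  for (j in seq_len(nPcs)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  scores <- xt %*% v
  rownames(scores) <- rownames(xt)
  scores
}

# Validate a genes x cells expression matrix; used at module boundaries.
.checkMatrix <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(sprintf("'%s' must be a numeric genes x cells matrix", arg))
  }
  if (nrow(m) < 1L || ncol(m) < 2L) {
    stop(sprintf("'%s' needs at least 1 gene and 2 cells", arg))
  }
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite entry at gene %d, cell %d", bad[1L], bad[2L]))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative entry at gene %d (%s), cell %d (%s)",
                 bad[1L], rownames(m)[bad[1L]] %||% "?",
                 bad[2L], colnames(m)[bad[2L]] %||% "?"))
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate cell identifiers")
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pearson correlation between the columns of two matrices (or within one),
# mapping undefined correlations (zero variance) to a supplied value.
.safeCor <- function(x, y = NULL, undefined = NA_real_) {
  cc <- suppressWarnings(stats::cor(x, y))
  cc[!is.finite(cc)] <- undefined
  cc
}
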