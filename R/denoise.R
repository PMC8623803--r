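#' Denoise expression by a random walk with restart
#'
#' Dropout zeros in one cell can be recovered from its neighbours in the
#' ensemble similarity network, because cells of the same type share
#' expression patterns. For every gene g, with e_g the gene's expression
#' across cells, the steady state of a random walk with restart over the
#' second-order transition matrix R solves
#' \deqn{(I - \alpha R) r_g = (1 - \alpha) e_g,}
#' which blends each cell's own signal (restart mass) with the averaged
#' signal of its network neighbourhood. Expression rows are used as the
#' restart distribution without renormalization, so with column-stochastic
#' R the total expression of each gene is conserved exactly.
#'
#' @param x normalized genes x cells matrix (restart distributions, one
#'   gene per row).
#' @param t a \linkS4class{TransitionMatrix} over the same cells.
#' @param alpha restart-weighting coefficient in [0, 1); default 0.7. With
#'   \code{alpha = 0} the input is returned unchanged.
#' @param solver \code{"direct"} (one dense LU factorization shared by all
#'   genes) or \code{"iterative"} (Richardson iteration of the fixed point).
#' @param tol residual tolerance: the max-norm residual of the linear
#'   system is checked for every gene.
#' @param maxIter iteration cap for the iterative solver.
#' @return genes x cells matrix of steady-state expression, entries >= 0,
#'   same dimnames as \code{x}. Cells isolated in the pruned network (unit
#'   self-loop) are preserved exactly.
#' @examples
#' R <- matrix(c(0, 1, 1, 0), 2, 2)
#' t <- new("TransitionMatrix", PE = R, R = R)
#' x <- matrix(c(1, 0), 1, 2, dimnames = list("g", c("a", "b")))
#' rwrSmooth(x, t, alpha = 0.5)  # 2/3, 1/3
#' @export
rwrSmooth <- function(x, t, alpha = 0.7, solver = c("direct", "iterative"),
                      tol = 1e-10, maxIter = 10000L) {
  solver <- match.arg(solver)
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  r2 <- t@R
  n <- ncol(x)
  if (nrow(r2) != n) stop("transition matrix and expression matrix disagree on N")
  if (alpha == 0) return(x)
  b <- (1 - alpha) * t(x)                    # N x M right-hand sides
  a <- diag(n) - alpha * r2
  if (solver == "direct") {
    sol <- solve(a, b)
  } else {
    sol <- b                                  # r <- alpha R r + (1-alpha) e
    for (it in seq_len(maxIter)) {
      nxt <- alpha * (r2 %*% sol) + b
      if (max(abs(nxt - sol)) < tol) { sol <- nxt; break }
      sol <- nxt
      if (it == maxIter) {
        stop(sprintf("RWR did not converge in %d iterations; worst residual %.3e",
                     maxIter, max(abs(a %*% sol - b))))
      }
    }
  }
  res <- max(abs(a %*% sol - b))
  if (res > max(tol, 1e-8)) {
    stop(sprintf("RWR residual %.3e exceeds tolerance", res))
  }
  out <- t(sol)
  minv <- min(out)
  if (minv < -1e-8) {
    stop(sprintf("negative steady-state expression (%.3e): transition matrix invalid", minv))
  }
  out[out < 0] <- 0                           # roundoff only, asserted above
  dimnames(out) <- dimnames(x)
  out
}
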