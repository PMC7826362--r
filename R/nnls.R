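#' Nonnegative least squares (Lawson-Hanson active set)
#'
#' Solves min ||A x - b||^2 subject to x >= 0 by the classical active-set
#' method, with a relative gradient tolerance and a generous iteration
#' budget so that heavily weighted (penalty-augmented) systems converge.
#'
#' @param A design matrix (m x n).
#' @param b response vector (length m).
#' @param tol optimality tolerance on the dual vector; default scales with
#'   the problem.
#' @param max_iter safeguard on active-set changes.
#' @return the nonnegative solution vector.
#' @export
nnls_lawson_hanson <- function(A, b, tol = NULL, max_iter = NULL) {
  A <- as.matrix(A)
  n <- ncol(A)
  tol <- tol %||% (10 * .Machine$double.eps * max(abs(A)) * max(dim(A)))
  max_iter <- max_iter %||% (50L * n + 50L)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol && iter < max_iter) {
    iter <- iter + 1L
    cand <- which(!passive)
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[passive][is.na(z[passive])] <- 0
      if (all(z[passive] > 0)) {
        x <- z
        break
      }
      neg <- passive & z <= 0
      ratio <- x[neg] / (x[neg] - z[neg])
      ratio[!is.finite(ratio)] <- 0
      alpha <- min(ratio)
      x <- x + alpha * (z - x)
      drop_tol <- 1e-12 * max(abs(x), 1e-300)
      passive[passive & x <= drop_tol] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) {
        x <- numeric(n)
        break
      }
    }
    w <- crossprod(A, b - A %*% x)
  }
  pmax(x, 0)
}
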