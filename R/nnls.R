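# Lawson-Hanson active-set non-negative least squares.
# Solves min_{x >= 0} ||A x - b||^2 for small numbers of unknowns (here the
# cluster count c), which is the regime of the centroid refit.

nnls_solve <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  n <- ncol(A)
  if (is.null(tol)) tol <- 1e-10 * max(1, max(abs(A))) * max(1, max(abs(b)))
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- drop(crossprod(A, b))
  iter <- 0L
  max_outer <- 3L * n + 10L
  while (iter < max_outer) {
    iter <- iter + 1L
    w <- drop(crossprod(A, b - A %*% x))
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      s <- numeric(n)
      fit <- tryCatch(qr.solve(A[, P, drop = FALSE], b),
                      error = function(e) NULL)
      if (is.null(fit)) {  # rank deficient: ridge-stabilized inner solve
        G <- crossprod(A[, P, drop = FALSE])
        fit <- solve(G + diag(1e-12, length(P)),
                     crossprod(A[, P, drop = FALSE], b))
      }
      s[P] <- fit
      if (all(s[P] > tol)) { x <- s; break }
      drop_set <- P[s[P] <= tol]
      alpha <- min(x[drop_set] / (x[drop_set] - s[drop_set]))
      x <- x + alpha * (s - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) { x[] <- 0; break }
    }
  }
  pmax(x, 0)
}
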