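# Non-negative matrix factorization: multiplicative updates, reference
# centroids, component matching, fixed-membership centroid refit, and the
# cluster-centroid consistency loss used by the generator objective.

.EPS <- 1e-12

# Seeded initialization. U0 is random uniform scaled by sqrt(mean(Y)/c);
# V0 is derived from Y %*% t(U0) (rescaled to a comparable magnitude) so
# each sample's initial membership depends only on its own row. This makes
# the whole factorization equivariant under row permutation, which the
# centroid loss relies on.
nmf_init <- function(Y, c, seed) {
  q <- ncol(Y)
  scale <- sqrt(max(mean(Y), .EPS) / c)
  U0 <- with_local_seed(seed, matrix(stats::runif(c * q), c, q)) * scale
  V0 <- Y %*% t(U0)
  mv <- mean(V0)
  if (mv > .EPS) V0 <- V0 * (scale / mv)
  list(V = V0, U = U0)
}

nmf_objective <- function(Y, V, U) sum((Y - V %*% U)^2)

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix `Y` (samples x features) as `V %*% U`
#' with `V >= 0` (m x c memberships) and `U >= 0` (c x q centroids),
#' minimizing the squared Frobenius reconstruction error with the classical
#' multiplicative update rule, whose objective is non-increasing at every
#' iteration. After convergence each column of `V` is rescaled to unit
#' maximum and the scale absorbed into the matching row of `U`.
#'
#' @param Y non-negative numeric matrix (or [OmicsMatrix-class]).
#' @param c integer cluster count, at most `min(dim(Y))`.
#' @param seed integer seed for the random initialization.
#' @param maxIter maximum number of update iterations (a high cap is used
#'   so small problems run to convergence).
#' @param tol relative objective-change stopping threshold.
#' @param init optional list with elements `V`, `U` overriding the seeded
#'   initialization (used for cross-checks against reference loops).
#' @return An [NMFFactors-class].
#' @examples
#' Y <- matrix(1:30, 6, 5)
#' f <- nmfDecompose(Y, c = 2, seed = 1)
#' reconError(f)
#' @export
nmfDecompose <- function(Y, c, seed = 1L, maxIter = 1000L, tol = 1e-4,
                         init = NULL) {
  if (is(Y, "OmicsMatrix")) Y <- exprValues(Y)
  Y <- as.matrix(Y)
  if (any(Y < 0)) stopf("NMF requires a non-negative matrix")
  if (any(!is.finite(Y))) stopf("NMF requires finite values")
  c <- as.integer(c)
  if (c < 1L || c > min(dim(Y)))
    stopf("cluster count c = %d must lie in [1, %d]", c, min(dim(Y)))
  if (maxIter < 1L) stopf("maxIter must be >= 1")
  if (is.null(init)) init <- nmf_init(Y, c, seed)
  V <- init$V
  U <- init$U
  obj <- numeric(maxIter)
  prev <- nmf_objective(Y, V, U)
  for (it in seq_len(maxIter)) {
    U <- U * (crossprod(V, Y) / (crossprod(V, V %*% U) + .EPS))
    V <- V * ((Y %*% t(U)) / (V %*% tcrossprod(U) + .EPS))
    cur <- nmf_objective(Y, V, U)
    obj[it] <- cur
    if (abs(prev - cur) <= tol * max(prev, .EPS)) {
      obj <- obj[seq_len(it)]
      break
    }
    prev <- cur
  }
  # unit-max normalization of V columns, scale into U rows
  sc <- apply(V, 2L, max)
  pos <- sc > 0
  V[, pos] <- sweep(V[, pos, drop = FALSE], 2L, sc[pos], "/")
  U[pos, ] <- sweep(U[pos, , drop = FALSE], 1L, sc[pos], "*")
  new("NMFFactors", V = V, U = U, c = c,
      reconError = frobenius(Y - V %*% U),
      objectiveTrace = obj)
}

.centroid_cache <- new.env(parent = emptyenv())

#' Reference cluster centroids of the observed target modality
#'
#' Decomposes the training-split target matrix once and caches the result;
#' the returned centroid matrix `U` is the fixed reference the NMF loss
#' compares every generated mini-batch against. For exact consistency with
#' the loss pipeline, the centroids are re-solved by fixed-membership
#' non-negative least squares at the converged memberships (the same
#' refit the loss applies to generated batches), so a batch equal to the
#' reference data yields a loss of zero. The cache key covers the data,
#' the cluster count and the seed, so changing any of them triggers
#' recomputation.
#'
#' @inheritParams nmfDecompose
#' @param Y_train non-negative training-split target matrix.
#' @return An [NMFFactors-class] (identical across repeated calls).
#' @export
referenceCentroids <- function(Y_train, c, seed = 1L, maxIter = 1000L,
                               tol = 1e-4) {
  if (is(Y_train, "OmicsMatrix")) Y_train <- exprValues(Y_train)
  key <- rlang::hash(list(Y_train, as.integer(c), as.integer(seed),
                          as.integer(maxIter), tol))
  hit <- .centroid_cache[[key]]
  if (!is.null(hit)) return(hit)
  fac <- nmfDecompose(Y_train, c = c, seed = seed, maxIter = maxIter, tol = tol)
  U_refit <- refit_centroids_full(Y_train, basisMatrix(fac))$U
  fac <- new("NMFFactors", V = basisMatrix(fac), U = U_refit, c = fac@c,
             reconError = frobenius(Y_train - basisMatrix(fac) %*% U_refit),
             objectiveTrace = fac@objectiveTrace)
  .centroid_cache[[key]] <- fac
  fac
}

#' Optimal matching of unordered NMF components
#'
#' NMF components carry no intrinsic order, so comparing two centroid
#' matrices elementwise requires aligning their rows first. Returns the
#' permutation `perm` minimizing `sum_i ||U_ref[i, ] - U_hat[perm[i], ]||^2`,
#' solved exactly by the Hungarian algorithm.
#'
#' @param U_ref,U_hat centroid matrices of identical shape (c x q).
#' @return Integer permutation of `1:c`; `U_hat[perm, ]` is the aligned copy.
#' @export
matchComponents <- function(U_ref, U_hat) {
  U_ref <- as.matrix(U_ref)
  U_hat <- as.matrix(U_hat)
  if (!all(dim(U_ref) == dim(U_hat)))
    stopf("centroid matrices must have identical shape")
  cc <- nrow(U_ref)
  # cost[i, r] = squared distance between reference row i and candidate row r
  cost <- outer(rowSums(U_ref^2), rep(1, cc)) +
    outer(rep(1, cc), rowSums(U_hat^2)) - 2 * tcrossprod(U_ref, U_hat)
  solve_assignment(cost)
}

# Refit with bookkeeping of the per-column passive (free) sets, needed by
# the loss gradient.
refit_centroids_full <- function(Y_hat, V_hat, tol = 1e-10) {
  Y_hat <- as.matrix(Y_hat)
  V_hat <- as.matrix(V_hat)
  if (nrow(Y_hat) != nrow(V_hat)) stopf("row mismatch between Y_hat and V_hat")
  cc <- ncol(V_hat)
  q <- ncol(Y_hat)
  U <- matrix(0, cc, q)
  free_sets <- vector("list", q)
  for (j in seq_len(q)) {
    x <- nnls_solve(V_hat, Y_hat[, j])
    U[, j] <- x
    free_sets[[j]] <- which(x > tol)
  }
  list(U = U, free_sets = free_sets)
}

#' Fixed-membership centroid refit (non-negative least squares)
#'
#' Given generated data `Y_hat` and a fixed membership matrix `V_hat`,
#' solves `U_hat = argmin_{U >= 0} ||Y_hat - V_hat U||_F^2` one feature
#' column at a time. Because `V_hat` is held fixed, the map from `Y_hat`
#' to `U_hat` is (piecewise) linear, which is what makes the centroid
#' loss differentiable in the generator output.
#'
#' @param Y_hat non-negative matrix (b x q).
#' @param V_hat fixed non-negative membership matrix (b x c).
#' @return Non-negative centroid matrix `U_hat` (c x q). An all-zero
#'   column of `V_hat` yields an all-zero centroid row with a warning.
#' @export
refitCentroids <- function(Y_hat, V_hat) {
  V_hat <- as.matrix(V_hat)
  zero_cols <- colSums(V_hat) == 0
  if (any(zero_cols))
    warnf("membership column(s) %s are all zero; their centroid rows are zero",
          paste(which(zero_cols), collapse = ", "))
  refit_centroids_full(Y_hat, V_hat)$U
}

# Centroid distance with V_hat (and the component matching) held fixed;
# also returns the analytic gradient w.r.t. Y_hat under the fixed
# active-set linearization. Shared by nmfLoss and the trainer.
nmf_loss_fixedV <- function(Y_hat, V_hat, U_ref, perm = NULL, grad = FALSE) {
  rf <- refit_centroids_full(Y_hat, V_hat)
  U_hat <- rf$U
  if (is.null(perm)) perm <- matchComponents(U_ref, U_hat)
  D <- U_ref - U_hat[perm, , drop = FALSE]
  loss <- sum(D * D)
  out <- list(loss = loss, U_hat = U_hat, perm = perm)
  if (grad) {
    cc <- nrow(U_ref)
    dU <- matrix(0, cc, ncol(U_ref))
    dU[perm, ] <- -2 * D
    dY <- matrix(0, nrow(Y_hat), ncol(Y_hat))
    for (j in seq_len(ncol(Y_hat))) {
      F <- rf$free_sets[[j]]
      if (!length(F)) next
      G <- V_hat[, F, drop = FALSE]
      M <- tryCatch(G %*% chol2inv(chol(crossprod(G))),
                    error = function(e)
                      G %*% solve(crossprod(G) + diag(1e-10, length(F))))
      dY[, j] <- M %*% dU[F, j]
    }
    out$grad <- dY
  }
  out
}

#' NMF cluster-centroid consistency loss
#'
#' The penalty that lets samples without target-modality ground truth shape
#' training: the generated mini-batch is decomposed (memberships treated as
#' constants), centroids are refit by fixed-membership non-negative least
#' squares, rows are aligned to the reference centroids by optimal
#' assignment, and the squared Frobenius distance between the aligned
#' centroid matrices is returned.
#'
#' @param U_ref reference centroid matrix (c x q) from
#'   [referenceCentroids()].
#' @param Y_hat_batch generated non-negative batch (b x q), `b >= c`.
#' @param c cluster count.
#' @param seed seed for the batch decomposition.
#' @param maxIter iteration cap for the batch decomposition.
#' @return Non-negative scalar; 0 iff the aligned refit centroids equal
#'   the reference.
#' @export
nmfLoss <- function(U_ref, Y_hat_batch, c, seed = 1L, maxIter = 1000L) {
  nmf_loss_grad(U_ref, Y_hat_batch, c, seed, maxIter, grad = FALSE)$loss
}

nmf_loss_grad <- function(U_ref, Y_hat_batch, c, seed = 1L, maxIter = 1000L,
                          grad = TRUE) {
  Y_hat_batch <- as.matrix(Y_hat_batch)
  c <- as.integer(c)
  if (nrow(Y_hat_batch) < c)
    stopf("batch has %d rows but the NMF loss needs at least c = %d; use a larger batch",
          nrow(Y_hat_batch), c)
  if (ncol(Y_hat_batch) != ncol(U_ref))
    stopf("feature count mismatch between batch and reference centroids")
  fac <- nmfDecompose(pmax(Y_hat_batch, 0), c = c, seed = seed,
                      maxIter = maxIter)
  nmf_loss_fixedV(Y_hat_batch, basisMatrix(fac), as.matrix(U_ref), grad = grad)
}
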