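# Independent oracle implementations used to cross-check the production
# code. Deliberately written as plain textbook loops, sharing no code with
# the package internals.

# Textbook multiplicative-update NMF loop (Frobenius objective), run from
# a supplied initialization; returns factors and the per-iteration
# objective.
oracle_nmf_multiplicative <- function(Y, V, U, n_iter, tol = 0) {
  eps <- 1e-12
  obj <- numeric(0)
  prev <- sum((Y - V %*% U)^2)
  for (t in seq_len(n_iter)) {
    U <- U * (t(V) %*% Y) / (t(V) %*% V %*% U + eps)
    V <- V * (Y %*% t(U)) / (V %*% U %*% t(U) + eps)
    cur <- sum((Y - V %*% U)^2)
    obj <- c(obj, cur)
    if (abs(prev - cur) <= tol * max(prev, eps)) break
    prev <- cur
  }
  list(V = V, U = U, obj = obj)
}

# All permutations of a vector (recursion; used for c <= 6 only).
all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_permutations(v[-i]), function(p) c(v[i], p))))
}

# Brute-force minimal-cost assignment.
oracle_assignment <- function(cost) {
  n <- nrow(cost)
  best <- NULL
  best_cost <- Inf
  for (p in all_permutations(seq_len(n))) {
    cst <- sum(cost[cbind(seq_len(n), p)])
    if (cst < best_cost) {
      best_cost <- cst
      best <- p
    }
  }
  list(perm = best, cost = best_cost)
}

# Observed-minus-expected two-group log-rank chi-squared p-value,
# computed directly from the risk-set tables.
oracle_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2L)
  g1 <- unique(group)[1L]
  times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V1 <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V1 <- V1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V1 == 0) return(1)
  1 - pchisq((O1 - E1)^2 / V1, df = 1)
}

# Rank-based AUC (Mann-Whitney), independent of pROC.
oracle_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  (mean(rank(c(pos, neg))[seq_along(pos)]) - (length(pos) + 1) / 2) /
    length(neg)
}

# NMF centroid loss recomputed from oracle components only: oracle MU
# decomposition (from the package's init, the declared entry point),
# per-column NNLS by projected grid refinement, brute-force matching.
oracle_nnls_col <- function(A, b) {
  # tiny problems only: active-set over all subsets
  n <- ncol(A)
  best <- rep(0, n)
  best_r <- sum(b^2)
  subsets <- unlist(lapply(seq_len(n), function(k)
    combn(n, k, simplify = FALSE)), recursive = FALSE)
  for (S in subsets) {
    x <- rep(0, n)
    sol <- tryCatch(qr.solve(A[, S, drop = FALSE], b), error = function(e) NULL)
    if (is.null(sol) || any(sol < 0)) next
    x[S] <- sol
    r <- sum((b - A %*% x)^2)
    if (r < best_r - 1e-12) {
      best_r <- r
      best <- x
    }
  }
  best
}
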