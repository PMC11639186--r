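test_that("production solver matches the textbook multiplicative-update loop", {
  Y <- matrix(1:30, 6, 5, byrow = TRUE)
  for (seed in c(0L, 1L, 2L)) {
    init <- CrossImpute:::nmf_init(Y, 2L, seed)
    ref <- oracle_nmf_multiplicative(Y, init$V, init$U, n_iter = 2000L)
    fac <- nmfDecompose(Y, c = 2, seed = seed, maxIter = 2000L, tol = 0,
                        init = init)
    err_ref <- sqrt(tail(ref$obj, 1))
    expect_lt(abs(reconError(fac) - err_ref) / err_ref, 1e-6)
    # objective non-increasing at every iteration, both implementations
    expect_true(all(diff(fac@objectiveTrace) <= 1e-8))
    expect_true(all(diff(ref$obj) <= 1e-8))
  }
})

test_that("exact low-rank input is recovered nearly exactly", {
  set.seed(10)
  V0 <- matrix(runif(60), 20, 3)
  V0 <- sweep(V0, 2, apply(V0, 2, max), "/")
  U0 <- matrix(runif(24, 0.5, 2), 3, 8)
  Y <- V0 %*% U0
  fac <- nmfDecompose(Y, c = 3, seed = 4, maxIter = 5000L, tol = 1e-12)
  expect_lte(reconError(fac), 1e-3 * sqrt(sum(Y^2)))
  expect_true(all(basisMatrix(fac) >= 0))
  expect_true(all(centroidMatrix(fac) >= 0))
})

test_that("an all-zero sample row stays zero and contributes no error", {
  set.seed(2)
  Y <- matrix(runif(40, 0.1, 2), 10, 4)
  Y[3, ] <- 0
  fac <- nmfDecompose(Y, c = 2, seed = 1)
  expect_equal(unname(basisMatrix(fac)[3, ]), rep(0, 2))
  resid <- Y - basisMatrix(fac) %*% centroidMatrix(fac)
  expect_equal(sum(resid[3, ]^2), 0)
})

test_that("invalid NMF inputs are rejected", {
  expect_error(nmfDecompose(matrix(c(-1, 2, 3, 4), 2, 2), c = 1), "non-negative")
  expect_error(nmfDecompose(matrix(1:6, 2, 3), c = 3), "c = 3")
})

test_that("referenceCentroids caches deterministically and invalidates on new data", {
  set.seed(5)
  Y <- matrix(runif(60, 0, 2), 12, 5)
  a <- referenceCentroids(Y, c = 2, seed = 3)
  b <- referenceCentroids(Y, c = 2, seed = 3)
  expect_identical(centroidMatrix(a), centroidMatrix(b))
  Y2 <- Y
  Y2[1, 1] <- Y2[1, 1] + 1
  d <- referenceCentroids(Y2, c = 2, seed = 3)
  expect_false(identical(centroidMatrix(a), centroidMatrix(d)))
  # c = 1 degenerates to the non-negative rank-1 approximation
  r1 <- referenceCentroids(Y, c = 1, seed = 3)
  expect_identical(dim(centroidMatrix(r1)), c(1L, 5L))
})

test_that("component matching recovers permutations and equals brute force", {
  set.seed(8)
  U <- matrix(runif(20, 0, 2), 5, 4)
  p <- sample(5)
  # U_hat = U_ref rows scrambled by p: matching must invert the scramble
  perm <- matchComponents(U, U[p, ])
  expect_identical(U[p, ][perm, ], U)
  expect_identical(matchComponents(U, U), 1:5)
  for (cc in 3:5) {
    A <- matrix(runif(cc * 3), cc, 3)
    B <- matrix(runif(cc * 3), cc, 3)
    got <- matchComponents(A, B)
    cost <- as.matrix(dist(rbind(A, B)))[seq_len(cc), cc + seq_len(cc)]^2
    best <- oracle_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(cc), got)]), best$cost,
                 tolerance = 1e-10)
  }
  expect_error(matchComponents(matrix(0, 2, 2), matrix(0, 3, 2)), "shape")
})

test_that("fixed-membership centroid refit solves the NNLS problem", {
  set.seed(11)
  V <- matrix(runif(12, 0.1, 1), 4, 3)
  U0 <- matrix(runif(9, 0.2, 2), 3, 3)
  Y <- V %*% U0
  expect_equal(refitCentroids(Y, V), U0, tolerance = 1e-8)
  # linearity when no constraints are active
  expect_equal(refitCentroids(2 * Y, V), 2 * U0, tolerance = 1e-8)
  # clipped case: compare to exhaustive active-set oracle per column
  Vn <- matrix(runif(8, 0.1, 1), 4, 2)
  Yn <- matrix(rnorm(12), 4, 3)
  Yn <- pmax(Yn, 0)
  Yn[1, ] <- 0   # push a column toward an active constraint
  got <- refitCentroids(Yn, Vn)
  for (j in 1:3) {
    expect_equal(got[, j], oracle_nnls_col(Vn, Yn[, j]), tolerance = 1e-8)
  }
  # all-zero membership column yields a zero centroid row with a warning
  Vz <- cbind(V[, 1:2], 0)
  expect_warning(uz <- refitCentroids(Y, Vz), "all zero")
  expect_equal(unname(uz[3, ]), rep(0, 3))
})

test_that("centroid loss is zero on the reference data and permutation invariant", {
  set.seed(21)
  Ytr <- matrix(runif(30 * 6, 0, 2), 30, 6)
  ref <- referenceCentroids(Ytr, c = 3, seed = 9)
  U_ref <- centroidMatrix(ref)
  expect_lte(nmfLoss(U_ref, Ytr, c = 3, seed = 9), 1e-6)
  # row shuffles leave the loss unchanged (memberships shuffle with them)
  sh <- sample(nrow(Ytr))
  l1 <- nmfLoss(U_ref, Ytr, c = 3, seed = 9)
  l2 <- nmfLoss(U_ref, Ytr[sh, ], c = 3, seed = 9)
  expect_equal(l1, l2, tolerance = 1e-10)
  # batches smaller than c are refused
  expect_error(nmfLoss(U_ref, Ytr[1:2, ], c = 3, seed = 9), "larger batch")
})

test_that("doubling the data with fixed memberships shifts centroids by the reference", {
  set.seed(22)
  Ytr <- matrix(runif(20 * 5, 0.2, 2), 20, 5)
  ref <- referenceCentroids(Ytr, c = 2, seed = 4)
  V_ref <- basisMatrix(ref)
  U_ref <- centroidMatrix(ref)
  # refit of 2*Y at fixed V gives 2*U_ref, so the distance is ||U_ref||_F^2
  res <- CrossImpute:::nmf_loss_fixedV(2 * Ytr, V_ref, U_ref)
  expect_equal(res$loss, sum(U_ref^2), tolerance = 1e-6)
})

test_that("analytic centroid-loss gradient matches finite differences", {
  set.seed(13)
  b <- 8; q <- 5; cc <- 2
  V <- matrix(runif(b * cc, 0.2, 1), b, cc)
  Y <- V %*% matrix(runif(cc * q, 0.5, 2), cc, q) +
    matrix(runif(b * q, 0, 0.05), b, q)
  U_ref <- matrix(runif(cc * q, 0.5, 2), cc, q)
  res <- CrossImpute:::nmf_loss_fixedV(Y, V, U_ref, grad = TRUE)
  h <- 1e-6
  fd <- matrix(0, b, q)
  for (i in seq_len(b)) for (j in seq_len(q)) {
    Yp <- Y; Yp[i, j] <- Yp[i, j] + h
    Ym <- Y; Ym[i, j] <- Ym[i, j] - h
    fd[i, j] <- (CrossImpute:::nmf_loss_fixedV(Yp, V, U_ref, perm = res$perm)$loss -
                 CrossImpute:::nmf_loss_fixedV(Ym, V, U_ref, perm = res$perm)$loss) / (2 * h)
  }
  expect_lt(max(abs(fd - res$grad)) / max(abs(res$grad)), 1e-3)
})

test_that("full loss pipeline matches an all-oracle recomputation on small cases", {
  # oracle route: textbook MU loop from the same init, exhaustive NNLS,
  # brute-force assignment; production route: nmfLoss
  set.seed(31)
  for (rep in 1:3) {
    Ytr <- matrix(runif(8 * 6, 0.1, 2), 8, 6)
    cc <- 3
    ref <- referenceCentroids(Ytr, c = cc, seed = rep)
    U_ref <- centroidMatrix(ref)
    Yb <- matrix(runif(8 * 6, 0.1, 2), 8, 6)
    got <- nmfLoss(U_ref, Yb, c = cc, seed = rep + 50)
    init <- CrossImpute:::nmf_init(Yb, cc, rep + 50)
    dec <- oracle_nmf_multiplicative(Yb, init$V, init$U, n_iter = 1000L,
                                     tol = 1e-4)
    sc <- apply(dec$V, 2, max)
    Vn <- sweep(dec$V, 2, sc, "/")
    U_hat <- sapply(seq_len(ncol(Yb)), function(j) oracle_nnls_col(Vn, Yb[, j]))
    cost <- outer(seq_len(cc), seq_len(cc),
                  Vectorize(function(i, r) sum((U_ref[i, ] - U_hat[r, ])^2)))
    want <- oracle_assignment(cost)$cost
    expect_lt(abs(got - want) / max(want, 1e-8), 1e-5)
  }
})
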