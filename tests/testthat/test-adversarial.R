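# Helpers building tiny networks with hand-set weights so every loss term
# can be recomputed with explicit arithmetic.
tiny_generator <- function() {
  g <- makeGenerator(2, 2, hiddenDims = c(2L, 2L), seed = 1)
  g$net$W <- list(matrix(c(1, 0, 0, 1), 2, 2),       # layer 1
                  matrix(c(0.5, 0.25, 0.5, 0.75), 2, 2),
                  matrix(c(1, -1, 0.5, 1), 2, 2))    # output layer
  g$net$b <- list(c(0.1, -0.2), c(0, 0.1), c(0.05, -0.3))
  g
}

tiny_critic <- function() {
  cr <- makeCritic(2, hiddenDims = c(2L, 2L), clipValue = 0.5, seed = 2)
  cr$net$W <- list(matrix(c(0.3, -0.2, 0.1, 0.4), 2, 2),
                   matrix(c(0.2, 0.3, -0.1, 0.25), 2, 2),
                   matrix(c(0.4, -0.3), 2, 1))
  cr$net$b <- list(c(0.05, 0), c(0.1, -0.05), 0.2)
  cr
}

# Explicit forward pass written independently of the package internals.
hand_forward <- function(W, b, x, out_relu) {
  h1 <- pmax(as.numeric(x %*% W[[1]]) + b[[1]], 0)
  h2 <- pmax(as.numeric(h1 %*% W[[2]]) + b[[2]], 0)
  o <- as.numeric(h2 %*% W[[3]]) + b[[3]]
  if (out_relu) pmax(o, 0) else o
}

test_that("generator output is non-negative, shaped, and row-independent", {
  gen <- makeGenerator(5, 3, hiddenDims = c(8L, 8L), seed = 3)
  X <- matrix(rnorm(7 * 5, sd = 3), 7, 5)   # arbitrary signs in the input
  Y <- generateTarget(gen, X)
  expect_identical(dim(Y), c(7L, 3L))
  expect_true(all(Y >= 0))
  # feed-forward nets act per sample: batch row i equals the single-row pass
  for (i in c(1L, 4L, 7L))
    expect_equal(generateTarget(gen, X[i, , drop = FALSE]), Y[i, , drop = FALSE])
  # all-zero parameters force an all-zero output
  gen0 <- gen
  gen0$net$W <- lapply(gen0$net$W, function(w) w * 0)
  gen0$net$b <- lapply(gen0$net$b, function(x) x * 0)
  expect_true(all(generateTarget(gen0, X) == 0))
  expect_error(generateTarget(gen, X[, 1:3]), "features")
})

test_that("critic loss matches hand arithmetic and is antisymmetric", {
  # linear-regime hand instance: identity first layers, score(y) = y1 - y2
  cr <- makeCritic(2, hiddenDims = c(2L, 2L), clipValue = 1, seed = 1)
  cr$net$W <- list(diag(2), diag(2), matrix(c(1, -1), 2, 1))
  cr$net$b <- list(c(0, 0), c(0, 0), 0)
  Y_real <- rbind(c(1, 0), c(0, 1))
  Y_fake <- rbind(c(2, 0), c(0, 0))
  # mean fake score (1*2 + (-1)*0 + 1*0 + (-1)*0)/2 = 1; mean real = 0
  expect_equal(criticLoss(cr, Y_real, Y_fake), 1)
  expect_equal(criticLoss(cr, Y_fake, Y_real), -1)

  set.seed(4)
  cr2 <- tiny_critic()
  A <- matrix(runif(6), 3, 2)
  B <- matrix(runif(6), 3, 2)
  expect_equal(criticLoss(cr2, A, B), -criticLoss(cr2, B, A))
  expect_equal(criticLoss(cr2, A, A), 0)
  expect_error(criticLoss(cr2, A[0, , drop = FALSE], B), "non-empty")
})

test_that("weight clipping clamps, preserves interior values, and is idempotent", {
  cr <- makeCritic(3, hiddenDims = c(4L, 4L), clipValue = 0.01, seed = 5)
  cr$net$W[[1]][1, 1] <- 0.5
  cr$net$W[[2]][2, 2] <- -0.005
  clipped <- clipWeights(cr)
  expect_equal(clipped$net$W[[1]][1, 1], 0.01)
  expect_equal(clipped$net$W[[2]][2, 2], -0.005)
  expect_true(CrossImpute:::critic_params_in_box(clipped))
  again <- clipWeights(clipped)
  expect_identical(again$net$W, clipped$net$W)
  expect_identical(again$net$b, clipped$net$b)
})

test_that("composite generator loss equals independently computed terms", {
  gen <- tiny_generator()
  cr <- tiny_critic()
  X <- rbind(c(0.5, 1.0), c(1.5, 0.2), c(0.1, 0.1))
  Y_obs <- rbind(c(0.8, 0.3), c(0.2, 0.9))
  obs_idx <- c(1L, 3L)

  # independent recomputation: explicit per-row forward passes
  Y_hat <- t(apply(X, 1, function(x) hand_forward(gen$net$W, gen$net$b, x, TRUE)))
  scores <- apply(Y_hat, 1, function(y) hand_forward(cr$net$W, cr$net$b, y, FALSE))
  adv_hand <- -mean(scores)
  mse_hand <- mean((Y_obs - Y_hat[obs_idx, ])^2)

  # alpha = beta = 0: pure adversarial term
  l0 <- generatorLoss(cr, gen, X, adversarial = TRUE)
  expect_equal(l0$total, adv_hand, tolerance = 1e-9)
  expect_equal(l0$nmf, 0)
  expect_equal(l0$mse, 0)

  # NMF term via the all-oracle pipeline (textbook decomposition,
  # exhaustive NNLS, brute-force matching) with c = 2
  U_ref <- matrix(c(0.6, 0.2, 0.3, 0.9), 2, 2)
  init <- CrossImpute:::nmf_init(Y_hat, 2L, 7L)
  dec <- oracle_nmf_multiplicative(Y_hat, init$V, init$U, n_iter = 1000L,
                                   tol = 1e-4)
  Vn <- sweep(dec$V, 2, apply(dec$V, 2, max), "/")
  U_hat <- sapply(1:2, function(j) oracle_nnls_col(Vn, Y_hat[, j]))
  cost <- outer(1:2, 1:2,
                Vectorize(function(i, r) sum((U_ref[i, ] - U_hat[r, ])^2)))
  nmf_hand <- oracle_assignment(cost)$cost

  full <- generatorLoss(cr, gen, X, Y_obs = Y_obs, obsIndex = obs_idx,
                        U_ref = U_ref, alpha = 0.3, beta = 0.7, c = 2L,
                        seed = 7L)
  expect_equal(full$adversarial, adv_hand, tolerance = 1e-9)
  expect_equal(full$mse, mse_hand, tolerance = 1e-9)
  expect_equal(full$nmf, nmf_hand, tolerance = 1e-6)
  expect_equal(full$total, adv_hand + 0.3 * nmf_hand + 0.7 * mse_hand,
               tolerance = 1e-6)

  expect_warning(
    generatorLoss(cr, gen, X, Y_obs = NULL, obsIndex = integer(),
                  beta = 1, adversarial = FALSE),
    "no observed rows")
})

test_that("a small adversarial gradient step does not increase the generator objective", {
  set.seed(9)
  gen <- makeGenerator(4, 3, hiddenDims = c(6L, 6L), seed = 11)
  cr <- clipWeights(makeCritic(3, hiddenDims = c(6L, 4L), clipValue = 0.05,
                               seed = 12))
  X <- matrix(runif(8 * 4, 0, 2), 8, 4)
  obj <- function(g) -mean(criticScore(cr, generateTarget(g, X)))
  fw <- CrossImpute:::mlp_forward(gen$net, X, cache = TRUE)
  fwC <- CrossImpute:::mlp_forward(cr$net, fw$out, cache = TRUE)
  dY <- CrossImpute:::mlp_backward(cr$net, fwC,
                                   matrix(-1 / nrow(X), nrow(X), 1))$dX
  gr <- CrossImpute:::mlp_backward(gen$net, fw, dY)
  base <- obj(gen)
  step <- 1e-2
  ok <- FALSE
  for (h in step * 0.5^(0:8)) {       # step halving: descent for small steps
    g2 <- gen
    for (l in seq_len(g2$net$L)) {
      g2$net$W[[l]] <- g2$net$W[[l]] - h * gr$dW[[l]]
      g2$net$b[[l]] <- g2$net$b[[l]] - h * gr$db[[l]]
    }
    if (obj(g2) <= base + 1e-12) { ok <- TRUE; break }
  }
  expect_true(ok)
})
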