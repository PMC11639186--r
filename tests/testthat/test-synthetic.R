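test_that("simulation is reproducible, shaped, and non-negative", {
  spec <- syntheticSpec(seed = 17)
  a <- simulatePairedOmics(spec)
  b <- simulatePairedOmics(spec)
  expect_identical(exprValues(sourceOmics(a$dataset)),
                   exprValues(sourceOmics(b$dataset)))
  expect_identical(a$truth$heldTarget, b$truth$heldTarget)
  expect_identical(dim(sourceOmics(a$dataset)), c(400L, 60L))
  expect_identical(dim(targetOmics(a$dataset)), c(300L, 40L))
  expect_length(missingIds(a$dataset), 100L)      # round(0.25 * 400)
  expect_true(all(exprValues(sourceOmics(a$dataset)) >= 0))
  expect_true(all(exprValues(targetOmics(a$dataset)) >= 0))
  expect_true(all(a$truth$heldTarget >= 0))
})

test_that("missing count follows the half-up rounding convention", {
  s <- simulatePairedOmics(syntheticSpec(n = 50L, p = 8L, q = 6L, cTrue = 2L,
                                         missingFraction = 0.25, seed = 2))
  expect_length(missingIds(s$dataset), 13L)       # round(12.5) half-up
})

test_that("the noiseless linear world is exactly solvable by regression", {
  s <- simulatePairedOmics(syntheticSpec(n = 120L, p = 20L, q = 10L,
                                         cTrue = 3L, noiseSd = 0,
                                         seed = 23))
  plan <- makeSplit(s$dataset, 0.8, seed = 23)
  cm <- baselineRegressionImpute(s$dataset, plan)
  expect_lte(groundTruthMSE(cm, s$truth), 1e-10)
})

test_that("labels are near-balanced and survival carries a risk signal", {
  spec <- syntheticSpec(seed = 29)
  s <- simulatePairedOmics(spec)
  frac <- mean(s$truth$labels$label)
  expect_gte(frac, 0.4)
  expect_lte(frac, 0.6)

  # ground-truth risk grouping separates survival in >= 90% of 50 seeds
  hits <- 0L
  for (sd in 1:50) {
    ss <- simulatePairedOmics(syntheticSpec(n = 120L, p = 10L, q = 8L,
                                            cTrue = 4L, seed = sd))
    risk <- (ss$truth$clusters - 1) / 3
    ids <- ss$truth$survival$sample_id
    gr <- list(low = ids[risk < 0.5], high = ids[risk >= 0.5])
    if (logrankPvalue(gr, ss$truth$survival) < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("cluster structure is recoverable and consistent across subsets", {
  s <- simulatePairedOmics(syntheticSpec(seed = 31))
  Y <- exprValues(targetOmics(s$dataset))
  fac <- nmfDecompose(Y, c = 4, seed = 1, maxIter = 2000L)
  expect_lte(reconError(fac), 0.15 * sqrt(sum(Y^2)))

  # centroids from a random half of the observed targets stay close to the
  # full-data centroids after optimal matching
  U_full <- centroidMatrix(fac)
  half <- with(list(n = nrow(Y)), {
    set.seed(7)
    sample(n, n %/% 2)
  })
  U_half <- centroidMatrix(nmfDecompose(Y[half, ], c = 4, seed = 1,
                                        maxIter = 2000L))
  perm <- matchComponents(U_full, U_half)
  d <- sqrt(sum((U_full - U_half[perm, ])^2))
  expect_lte(d, 0.2 * sqrt(sum(U_full^2)))
})

test_that("ground-truth MSE measures imputed rows only", {
  s <- simulatePairedOmics(syntheticSpec(n = 60L, p = 8L, q = 5L, cTrue = 2L,
                                         seed = 3))
  ds <- s$dataset
  perfect <- CrossImpute:::completed_from_rows(ds, s$truth$heldTarget)
  expect_equal(groundTruthMSE(perfect, s$truth), 0)
  shifted <- CrossImpute:::completed_from_rows(ds, s$truth$heldTarget + 1)
  expect_equal(groundTruthMSE(shifted, s$truth), 1)
  short <- s$truth$heldTarget[-1, , drop = FALSE]
  expect_error(groundTruthMSE(perfect, short), "missing for imputed")
})

test_that("the column-mean imputer sets a stable baseline bar on the benchmark", {
  s <- simulatePairedOmics(syntheticSpec(seed = 1))
  mse <- groundTruthMSE(baselineMeanImpute(s$dataset), s$truth)
  # pinned from the benchmark design: between-cluster variance dominates
  expect_gte(mse, 0.05)
  expect_lte(mse, 0.25)
})

test_that("kNN baseline follows its weighting contract", {
  ds <- tiny_paired(n = 10L, p = 3L, q = 2L, k = 2L, seed = 12)
  # duplicate an observed source row into a missing sample: k = 1 copies
  # that sample's target row exactly
  X <- exprValues(sourceOmics(ds))
  X[missingIds(ds)[1], ] <- X[observedIds(ds)[2], ]
  ds2 <- alignSamples(omicsMatrix(X), targetOmics(ds))
  cm <- baselineKnnImpute(ds2, kNeighbors = 1L)
  expect_equal(exprValues(cm)[missingIds(ds2)[1], ],
               exprValues(targetOmics(ds2))[observedIds(ds2)[2], ])
  # hand-computed inverse-distance weights on a 3-observed instance
  ids <- c("o1", "o2", "o3", "m1")
  Xs <- matrix(c(1, 2, 100, 0), 4, 1, dimnames = list(ids, "x"))
  Yt <- matrix(c(1, 4, 1000), 3, 1, dimnames = list(ids[1:3], "y"))
  dsh <- alignSamples(omicsMatrix(Xs), omicsMatrix(Yt))
  cmh <- baselineKnnImpute(dsh, kNeighbors = 2L)
  expect_equal(unname(exprValues(cmh)["m1", ]), (1 / 1 * 1 + 1 / 2 * 4) / (1.5))
  # k = m averages every observed target row
  cma <- baselineKnnImpute(dsh, kNeighbors = 3L)
  w <- c(1, 1 / 2, 1 / 100); w <- w / sum(w)
  expect_equal(unname(exprValues(cma)["m1", ]), sum(w * c(1, 4, 1000)))
  expect_error(baselineKnnImpute(dsh, kNeighbors = 5L), "exceeds")
})

test_that("regression baseline handles exact, independent, and constant targets", {
  set.seed(60)
  n <- 60L
  ids <- sprintf("R%02d", 1:n)
  X <- matrix(runif(n * 4, 0, 2), n, 4, dimnames = list(ids, paste0("x", 1:4)))
  Y <- cbind(lin = 2 * X[, 1], const = rep(1.5, n))
  rownames(Y) <- ids
  ds <- alignSamples(omicsMatrix(X), omicsMatrix(Y[1:48, , drop = FALSE]))
  plan <- makeSplit(ds, 0.8, seed = 60)
  cm <- baselineRegressionImpute(ds, plan)
  mis <- missingIds(ds)
  expect_lte(mean((exprValues(cm)[mis, "lin"] - Y[mis, "lin"])^2), 1e-10)
  expect_lte(mean((exprValues(cm)[mis, "const"] - 1.5)^2), 1e-20)
  # target independent of source: held-out MSE near the target variance
  Yind <- cbind(a = runif(n, 0, 2))
  rownames(Yind) <- ids
  dsi <- alignSamples(omicsMatrix(X), omicsMatrix(Yind[1:48, , drop = FALSE]))
  cmi <- baselineRegressionImpute(dsi, makeSplit(dsi, 0.8, seed = 61))
  mse <- mean((exprValues(cmi)[missingIds(dsi), "a"] -
                 Yind[missingIds(dsi), "a"])^2)
  expect_lt(abs(mse - var(Yind[, "a"])) / var(Yind[, "a"]), 0.5)
})
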