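# Baseline imputers: cross-omics k-nearest-neighbour averaging and
# per-feature linear regression.

#' k-nearest-neighbour cross-omics imputation
#'
#' For each missing sample, finds its `kNeighbors` nearest observed
#' samples by Euclidean distance in the source modality and imputes the
#' target row as the inverse-distance-weighted mean of the neighbours'
#' target rows (uniform weights over exact matches when a distance is 0).
#'
#' @param ds an aligned [PairedOmicsDataset-class].
#' @param kNeighbors neighbourhood size, at most the number of observed
#'   samples.
#' @return A [CompletedMatrix-class].
#' @export
baselineKnnImpute <- function(ds, kNeighbors = 5L) {
  stopifnot(is(ds, "PairedOmicsDataset"))
  obs <- observedIds(ds); mis <- missingIds(ds)
  m <- length(obs)
  if (kNeighbors > m)
    stopf("kNeighbors (%d) exceeds the number of observed samples (%d)",
          kNeighbors, m)
  X <- exprValues(sourceOmics(ds))
  Y <- exprValues(targetOmics(ds))
  Xobs <- X[obs, , drop = FALSE]
  imputed <- matrix(0, length(mis), ncol(Y),
                    dimnames = list(mis, colnames(Y)))
  for (id in mis) {
    d <- sqrt(rowSums(sweep(Xobs, 2L, X[id, ], "-")^2))
    nb <- order(d)[seq_len(kNeighbors)]
    dn <- d[nb]
    w <- if (any(dn == 0)) as.numeric(dn == 0) else 1 / dn
    w <- w / sum(w)
    imputed[id, ] <- drop(w %*% Y[obs[nb], , drop = FALSE])
  }
  completed_from_rows(ds, imputed)
}

#' Per-feature linear-regression imputation
#'
#' Ordinary least squares of each target feature on all source features,
#' fit on the training split and applied to the missing samples;
#' predictions are clipped at zero to preserve non-negativity. When there
#' are more source features than training samples the normal equations
#' are ridge-stabilized (with a warning).
#'
#' @param ds an aligned [PairedOmicsDataset-class].
#' @param plan a [SplitPlan-class]; the fit uses its training ids.
#' @return A [CompletedMatrix-class].
#' @export
baselineRegressionImpute <- function(ds, plan) {
  stopifnot(is(ds, "PairedOmicsDataset"), is(plan, "SplitPlan"))
  tr <- trainIds(plan)
  if (length(tr) < 2L) stopf("need at least 2 training samples")
  X <- exprValues(sourceOmics(ds))
  Y <- exprValues(targetOmics(ds))
  mis <- missingIds(ds)
  Xtr <- cbind(1, X[tr, , drop = FALSE])
  Ytr <- Y[tr, , drop = FALSE]
  if (ncol(Xtr) > nrow(Xtr)) {
    warnf("more source features (%d) than training samples (%d); using ridge-stabilized fit",
          ncol(Xtr) - 1L, nrow(Xtr))
    G <- crossprod(Xtr) + diag(1e-6, ncol(Xtr))
    B <- solve(G, crossprod(Xtr, Ytr))
  } else {
    B <- qr.coef(qr(Xtr), Ytr)
    B[is.na(B)] <- 0          # aliased columns contribute nothing
  }
  pred <- pmax(cbind(1, X[mis, , drop = FALSE]) %*% B, 0)
  rownames(pred) <- mis
  completed_from_rows(ds, pred)
}

#' Column-mean imputation
#'
#' The weakest baseline: every missing sample receives the column means of
#' the observed target rows. Used as the reference bar in benchmarking.
#'
#' @param ds an aligned [PairedOmicsDataset-class].
#' @return A [CompletedMatrix-class].
#' @export
baselineMeanImpute <- function(ds) {
  stopifnot(is(ds, "PairedOmicsDataset"))
  Y <- exprValues(targetOmics(ds))
  mis <- missingIds(ds)
  mu <- colMeans(Y)
  imputed <- matrix(mu, length(mis), ncol(Y), byrow = TRUE,
                    dimnames = list(mis, colnames(Y)))
  completed_from_rows(ds, imputed)
}
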