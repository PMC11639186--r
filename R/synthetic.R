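# Synthetic paired-omics simulator with known ground truth. Emulates the
# statistical structure the imputation model assumes: two non-negative
# modalities sharing latent cluster memberships, a (possibly non-linear)
# source-to-target map, a completely missing sample subset, binary
# phenotype labels tied to the clusters, and survival times tied to a
# cluster-determined latent risk.

#' Synthetic paired-omics specification
#'
#' Defaults define the package's benchmark condition: 400 samples, 60
#' source and 40 target features, 4 well-separated latent clusters, 25%
#' of samples missing in the target modality, a linear cluster-to-feature
#' map with truncated Gaussian noise (sd 0.05), labels splitting the
#' clusters evenly, and exponential survival with a unit log-hazard slope
#' on the latent risk and 20% censoring.
#'
#' @param n total sample count.
#' @param p,q source and target feature counts.
#' @param cTrue latent cluster count.
#' @param missingFraction fraction of samples with the target row
#'   withheld, in (0, 1).
#' @param mapKind `"linear"` (identity map on the cluster signal) or
#'   `"mlp_nonlinear"` (fixed seeded softplus one-hidden-layer positive
#'   map).
#' @param noiseSd standard deviation of the truncated-at-zero Gaussian
#'   measurement noise.
#' @param labelRule function from cluster index to binary label; default
#'   splits the clusters into two equal halves.
#' @param hazardCoef log hazard ratio per unit latent risk.
#' @param censorRate expected fraction of censored samples, in [0, 1).
#' @param seed master seed.
#' @return Specification list of class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(n = 400L, p = 60L, q = 40L, cTrue = 4L,
                          missingFraction = 0.25,
                          mapKind = c("linear", "mlp_nonlinear"),
                          noiseSd = 0.05, labelRule = NULL,
                          hazardCoef = 1, censorRate = 0.2, seed = 1L) {
  mapKind <- match.arg(mapKind)
  if (n < cTrue || cTrue < 1L) stopf("need n >= cTrue >= 1")
  if (missingFraction <= 0 || missingFraction >= 1)
    stopf("missingFraction must lie in (0, 1)")
  if (noiseSd < 0) stopf("noiseSd must be >= 0")
  if (censorRate < 0 || censorRate >= 1) stopf("censorRate must lie in [0, 1)")
  if (is.null(labelRule))
    labelRule <- function(z) as.integer(z > ceiling(cTrue / 2))
  structure(list(n = as.integer(n), p = as.integer(p), q = as.integer(q),
                 cTrue = as.integer(cTrue),
                 missingFraction = missingFraction, mapKind = mapKind,
                 noiseSd = noiseSd, labelRule = labelRule,
                 hazardCoef = hazardCoef, censorRate = censorRate,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Simulate a paired omics dataset with ground truth
#'
#' Draws uniform cluster assignments, near-one-hot Dirichlet-jittered
#' memberships `V_true`, non-negative centroid matrices for both
#' modalities (with a pairwise centroid-separation check against the
#' noise level), builds `X = V_true U_x + noise` and
#' `Y = map(V_true U_y) + noise` (both truncated at zero), withholds a
#' seeded `missingFraction` of target rows as ground truth, and attaches
#' cluster-determined binary labels and exponential survival times with
#' independent censoring. Fully reproducible per seed.
#'
#' @param spec a [syntheticSpec()].
#' @return List with elements `dataset` (a [PairedOmicsDataset-class]
#'   whose target lacks the withheld rows) and `truth` (list: `heldTarget`
#'   matrix of withheld rows, `labels` and `survival` data.frames over all
#'   samples, `clusters`, `Vtrue`, `Uy`).
#' @export
simulatePairedOmics <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_local_seed(spec$seed, {
    n <- spec$n; p <- spec$p; q <- spec$q; cc <- spec$cTrue
    z <- sample.int(cc, n, replace = TRUE)
    # near-one-hot memberships with Dirichlet jitter
    jit <- matrix(stats::rgamma(n * cc, shape = 1), n, cc)
    jit <- jit / rowSums(jit)
    V <- 0.85 * diag(cc)[z, , drop = FALSE] + 0.15 * jit
    Ux <- matrix(stats::runif(cc * p, 0.5, 2), cc, p)
    Uy <- matrix(stats::runif(cc * q, 0.5, 2), cc, q)
    min_sep <- function(U) {
      d <- as.matrix(stats::dist(U))
      min(d[upper.tri(d)])
    }
    if (cc > 1L && (min_sep(Ux) < 4 * spec$noiseSd ||
                    min_sep(Uy) < 4 * spec$noiseSd))
      stopf("centroids are closer than 4 * noiseSd; lower noiseSd")
    X <- pmax(V %*% Ux + matrix(stats::rnorm(n * p, sd = spec$noiseSd), n, p), 0)
    M <- V %*% Uy
    if (spec$mapKind == "mlp_nonlinear") {
      h <- max(8L, q %/% 2L)
      W1 <- matrix(stats::rnorm(q * h, sd = 1 / sqrt(q)), q, h)
      W2 <- matrix(abs(stats::rnorm(h * q, sd = 1 / h)), h, q)
      raw <- log1p(exp(M %*% W1)) %*% W2        # softplus, positive weights
      M <- raw * (mean(M) / mean(raw))
    }
    Yfull <- pmax(M + matrix(stats::rnorm(n * q, sd = spec$noiseSd), n, q), 0)
    ids <- sprintf("S%04d", seq_len(n))
    rownames(X) <- ids; colnames(X) <- sprintf("src%03d", seq_len(p))
    rownames(Yfull) <- ids; colnames(Yfull) <- sprintf("tgt%03d", seq_len(q))
    k <- as.integer(round_half_up(spec$missingFraction * n))
    mis <- sort(sample.int(n, k))
    mis_ids <- ids[mis]
    obs_ids <- ids[-mis]

    labels <- data.frame(sample_id = ids, label = spec$labelRule(z),
                         stringsAsFactors = FALSE)
    risk <- (z - 1) / max(cc - 1, 1)
    rate <- 0.01 * exp(spec$hazardCoef * risk)
    t_event <- stats::rexp(n, rate = rate)
    censored <- stats::runif(n) < spec$censorRate
    time <- ifelse(censored, stats::runif(n, 0, t_event), t_event)
    survival <- data.frame(sample_id = ids, time = time,
                           event = as.integer(!censored),
                           stringsAsFactors = FALSE)

    ds <- alignSamples(omicsMatrix(X),
                       omicsMatrix(Yfull[obs_ids, , drop = FALSE]))
    list(dataset = ds,
         truth = list(heldTarget = Yfull[mis_ids, , drop = FALSE],
                      labels = labels, survival = survival,
                      clusters = z, Vtrue = V, Uy = Uy))
  })
}

#' MSE of imputed rows against withheld ground truth
#'
#' @param completed a [CompletedMatrix-class].
#' @param truth the `truth` element returned by [simulatePairedOmics()]
#'   (or any list with a `heldTarget` matrix), or a bare matrix of
#'   withheld rows.
#' @return Scalar MSE over the imputed rows only.
#' @export
groundTruthMSE <- function(completed, truth) {
  stopifnot(is(completed, "CompletedMatrix"))
  held <- if (is.list(truth) && !is.null(truth$heldTarget)) truth$heldTarget
  else as.matrix(truth)
  imp_ids <- sampleIds(completed)[provenance(completed) == "imputed"]
  gap <- setdiff(imp_ids, rownames(held))
  if (length(gap))
    stopf("ground truth missing for imputed sample(s): %s",
          paste(utils::head(gap, 5L), collapse = ", "))
  mean((exprValues(completed)[imp_ids, , drop = FALSE] -
          held[imp_ids, , drop = FALSE])^2)
}
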