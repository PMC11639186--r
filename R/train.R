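# Adversarial training loop and imputation.

#' Training configuration
#'
#' Validates and assembles the hyperparameters of the adversarial
#' imputation trainer.
#'
#' @param alpha weight of the NMF centroid-consistency loss (>= 0).
#' @param beta weight of the MSE reconstruction loss (>= 0).
#' @param c NMF cluster count, default 10.
#' @param epochs training epochs, default 50.
#' @param batchSize mini-batch size, default 64 (must be >= `c` when the
#'   NMF loss is active).
#' @param criticSteps critic updates per generator update, default 5.
#' @param learningRate RMSprop learning rate for both networks.
#' @param clipValue critic weight-clip half-width, default 0.01.
#' @param seed master seed; all randomness (initialization, shuffles,
#'   batch decompositions) flows from it through named sub-streams.
#' @param mode `"full"` (all three generator terms), `"nmf_only"`
#'   (reconstruction term off) or `"mse_only"` (pure feed-forward MSE
#'   network, no adversarial or NMF term -- the classical baseline).
#' @param genHidden,criticHidden hidden-layer widths of the two networks.
#' @param nmfMaxIter iteration cap for the per-batch NMF decomposition.
#' @return Validated configuration list of class `"TrainingConfig"`.
#' @export
trainingConfig <- function(alpha = 1e-4, beta = 1.0, c = 10L, epochs = 50L,
                           batchSize = 64L, criticSteps = 5L,
                           learningRate = 5e-3, clipValue = 0.01, seed = 1L,
                           mode = c("full", "nmf_only", "mse_only"),
                           genHidden = c(512L, 768L),
                           criticHidden = c(256L, 128L),
                           nmfMaxIter = 500L) {
  mode <- match.arg(mode)
  if (alpha < 0 || beta < 0) stopf("alpha and beta must be non-negative")
  if (learningRate <= 0) stopf("learningRate must be positive")
  if (clipValue <= 0) stopf("clipValue must be positive")
  if (epochs < 0) stopf("epochs must be >= 0")
  c <- as.integer(c)
  if (mode == "nmf_only") beta <- 0
  if (mode == "mse_only") alpha <- 0
  if (alpha > 0 && batchSize < c)
    stopf("batchSize (%d) must be >= cluster count c (%d) when alpha > 0",
          batchSize, c)
  structure(list(alpha = alpha, beta = beta, c = c,
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 criticSteps = as.integer(criticSteps),
                 learningRate = learningRate, clipValue = clipValue,
                 seed = as.integer(seed), mode = mode,
                 genHidden = as.integer(genHidden),
                 criticHidden = as.integer(criticHidden),
                 nmfMaxIter = as.integer(nmfMaxIter)),
            class = "TrainingConfig")
}

# Split a shuffled id vector into batches; when the NMF loss is active a
# trailing batch smaller than c is merged into its predecessor.
make_batches <- function(ids, batch_size, min_last = 1L) {
  n <- length(ids)
  if (n == 0L) return(list())
  starts <- seq(1L, n, by = batch_size)
  batches <- lapply(starts, function(s) ids[s:min(s + batch_size - 1L, n)])
  nb <- length(batches)
  if (nb > 1L && length(batches[[nb]]) < min_last) {
    batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
    batches[[nb]] <- NULL
  }
  batches
}

#' Train the adversarial imputer
#'
#' Runs the full training procedure: per mini-batch (drawn with a seeded
#' shuffle from the union of training and missing sample ids), the critic
#' takes `criticSteps` RMSprop updates on real observed-target rows versus
#' the generated counterparts of the same samples, each followed by weight
#' clipping, and the generator then takes one update on the composite
#' objective -- adversarial and centroid terms over every batch row,
#' reconstruction restricted to rows with observed targets. The reference
#' centroid matrix is computed once from the training-split target rows
#' before the first epoch. The parameters with the best validation MSE
#' across epochs are kept.
#'
#' @param ds an aligned [PairedOmicsDataset-class].
#' @param plan a [SplitPlan-class] consistent with `ds`.
#' @param cfg a configuration from [trainingConfig()].
#' @param criticMonitor optional function called with the critic after
#'   every critic update (used to assert training invariants such as the
#'   weight-clip box).
#' @return A [TrainedImputer-class].
#' @export
trainImputer <- function(ds, plan, cfg = trainingConfig(),
                         criticMonitor = NULL) {
  stopifnot(is(ds, "PairedOmicsDataset"), is(plan, "SplitPlan"),
            inherits(cfg, "TrainingConfig"))
  if (!setequal(c(trainIds(plan), validationIds(plan)), observedIds(ds)))
    stopf("split plan is inconsistent with the dataset's observed samples")
  X <- exprValues(sourceOmics(ds))
  Y <- exprValues(targetOmics(ds))
  p <- ncol(X); q <- ncol(Y)
  tr <- trainIds(plan); va <- validationIds(plan); mi <- missingIds(plan)
  adversarial <- cfg$mode != "mse_only"

  gen <- makeGenerator(p, q, cfg$genHidden, seed = sub_seed(cfg$seed, "gen_init"))
  # warm-start the output layer at the training-target column means with
  # small weights: with a rectified output layer, a symmetric full-scale
  # init either leaves output units permanently dead on all-positive
  # expression data or produces a huge first-epoch transient whose
  # correction kills them; starting at the mean profile avoids both
  gen$net$b[[gen$net$L]] <- colMeans(Y[tr, , drop = FALSE])
  gen$net$W[[gen$net$L]] <- gen$net$W[[gen$net$L]] * 0.01
  critic <- makeCritic(q, cfg$criticHidden, clipValue = cfg$clipValue,
                       seed = sub_seed(cfg$seed, "critic_init"))
  g_state <- rmsprop_state(gen$net)
  c_state <- rmsprop_state(critic$net)

  U_ref <- matrix(0, 0L, 0L)
  if (cfg$alpha > 0) {
    if (length(tr) < cfg$c)
      stopf("training split (%d samples) smaller than cluster count c = %d",
            length(tr), cfg$c)
    U_ref <- centroidMatrix(referenceCentroids(
      Y[tr, , drop = FALSE], c = cfg$c, seed = sub_seed(cfg$seed, "ref_nmf"),
      maxIter = 1000L))
  }

  pool <- c(tr, mi)
  obs_set <- tr
  X_val <- X[va, , drop = FALSE]
  Y_val <- Y[va, , drop = FALSE]

  hist_rows <- vector("list", cfg$epochs)
  best_val <- Inf
  best_gen <- gen
  best_epoch <- integer()

  for (epoch in seq_len(cfg$epochs)) {
    perm <- with_local_seed(sub_seed(cfg$seed, paste0("shuffle", epoch)),
                            sample(pool))
    batches <- make_batches(perm, cfg$batchSize,
                            min_last = if (cfg$alpha > 0) cfg$c else 1L)
    ep <- c(critic = 0, adv = 0, nmf = 0, mse = 0)
    nb <- 0L
    for (bi in seq_along(batches)) {
      batch <- batches[[bi]]
      obs <- batch[batch %in% obs_set]
      obs_rows <- match(obs, batch)
      Xb <- X[batch, , drop = FALSE]
      b <- nrow(Xb)

      if (cfg$mode == "mse_only" && length(obs) == 0L) {
        warnf("skipping batch with no observed target rows in mse_only mode")
        next
      }

      closs <- NA_real_
      if (adversarial && length(obs) > 0L) {
        Y_real <- Y[obs, , drop = FALSE]
        Y_fake <- generateTarget(gen, X[obs, , drop = FALSE])
        bo <- nrow(Y_real)
        for (t in seq_len(cfg$criticSteps)) {
          fw <- mlp_forward(critic$net, rbind(Y_fake, Y_real), cache = TRUE)
          dOut <- matrix(c(rep(1 / bo, bo), rep(-1 / bo, bo)), ncol = 1L)
          gr <- mlp_backward(critic$net, fw, dOut)
          st <- rmsprop_step(critic$net, gr, c_state, cfg$learningRate)
          critic$net <- st$net; c_state <- st$state
          critic <- clipWeights(critic)
          if (!is.null(criticMonitor)) criticMonitor(critic)
        }
        closs <- criticLoss(critic, Y_real, Y_fake)
      }

      # generator step
      fwG <- mlp_forward(gen$net, Xb, cache = TRUE)
      Y_hat <- fwG$out
      dY <- matrix(0, b, q)
      adv_term <- 0
      if (adversarial) {
        fwC <- mlp_forward(critic$net, Y_hat, cache = TRUE)
        adv_term <- -mean(fwC$out)
        grC <- mlp_backward(critic$net, fwC,
                            matrix(-1 / b, b, 1L))
        dY <- dY + grC$dX
      }
      nmf_term <- 0
      if (cfg$alpha > 0) {
        nl <- nmf_loss_grad(U_ref, Y_hat, c = cfg$c,
                            seed = sub_seed(cfg$seed,
                                            paste0("nmf", epoch, "_", bi)),
                            maxIter = cfg$nmfMaxIter)
        nmf_term <- nl$loss
        dY <- dY + cfg$alpha * nl$grad
      }
      mse_term <- 0
      if (cfg$beta > 0 && length(obs) > 0L) {
        R <- Y_hat[obs_rows, , drop = FALSE] - Y[obs, , drop = FALSE]
        mse_term <- mean(R * R)
        dY[obs_rows, ] <- dY[obs_rows, ] +
          cfg$beta * 2 * R / length(R)
      }
      grG <- mlp_backward(gen$net, fwG, dY)
      st <- rmsprop_step(gen$net, grG, g_state, cfg$learningRate)
      gen$net <- st$net; g_state <- st$state

      ep <- ep + c(critic = if (is.na(closs)) 0 else closs,
                   adv = adv_term, nmf = nmf_term, mse = mse_term)
      nb <- nb + 1L
    }
    ep <- ep / max(nb, 1L)
    val_mse <- mean((generateTarget(gen, X_val) - Y_val)^2)
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, critic_loss = ep[["critic"]], adv_term = ep[["adv"]],
      nmf_term = ep[["nmf"]], mse_term = ep[["mse"]], val_mse = val_mse)
    if (val_mse < best_val) {
      best_val <- val_mse
      best_gen <- gen
      best_epoch <- epoch
    }
  }

  history <- if (cfg$epochs > 0L) do.call(rbind, hist_rows) else
    data.frame(epoch = integer(), critic_loss = numeric(),
               adv_term = numeric(), nmf_term = numeric(),
               mse_term = numeric(), val_mse = numeric())
  new("TrainedImputer",
      generator = if (length(best_epoch)) best_gen else gen,
      critic = critic, config = unclass(cfg), history = history,
      referenceU = U_ref, bestEpoch = as.integer(best_epoch))
}

#' Impute the missing target rows
#'
#' Applies the trained generator to the source profiles of the missing
#' samples only; observed samples keep their measured target rows
#' verbatim.
#'
#' @param imp a [TrainedImputer-class].
#' @param ds the aligned [PairedOmicsDataset-class] to complete.
#' @return A [CompletedMatrix-class] over all n source samples with
#'   per-sample provenance flags.
#' @export
imputeMissing <- function(imp, ds) {
  stopifnot(is(imp, "TrainedImputer"), is(ds, "PairedOmicsDataset"))
  X <- exprValues(sourceOmics(ds))
  Y <- exprValues(targetOmics(ds))
  if (ncol(X) != imp@generator$inputDim)
    stopf("source has %d features but the generator expects %d",
          ncol(X), imp@generator$inputDim)
  obs <- observedIds(ds); mis <- missingIds(ds)
  if (length(obs) == 0L)
    stopf("no observed target samples: reference data required for imputation")
  out <- matrix(0, nrow(X), ncol(Y),
                dimnames = list(c(obs, mis), colnames(Y)))
  out[obs, ] <- Y[obs, , drop = FALSE]
  if (length(mis))
    out[mis, ] <- generateTarget(imp@generator, X[mis, , drop = FALSE])
  new("CompletedMatrix", values = out,
      provenance = factor(rep(c("observed", "imputed"),
                              c(length(obs), length(mis))),
                          levels = c("observed", "imputed")))
}

#' Completed matrix from externally imputed rows
#'
#' Assembles a [CompletedMatrix-class] from the dataset's observed rows
#' plus a matrix of imputed rows (used by the baseline imputers).
#'
#' @param ds the aligned [PairedOmicsDataset-class].
#' @param imputed matrix of imputed target rows, rownames = missing ids.
#' @return A [CompletedMatrix-class].
#' @keywords internal
completed_from_rows <- function(ds, imputed) {
  obs <- observedIds(ds); mis <- missingIds(ds)
  Y <- exprValues(targetOmics(ds))
  out <- matrix(0, length(obs) + length(mis), ncol(Y),
                dimnames = list(c(obs, mis), colnames(Y)))
  out[obs, ] <- Y[obs, , drop = FALSE]
  if (length(mis)) out[mis, ] <- imputed[mis, , drop = FALSE]
  new("CompletedMatrix", values = out,
      provenance = factor(rep(c("observed", "imputed"),
                              c(length(obs), length(mis))),
                          levels = c("observed", "imputed")))
}
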