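# Generator and critic definitions and the adversarial loss terms.

#' Construct the generator network
#'
#' A fully connected encoder-decoder with two rectifier hidden layers
#' (default 512 and 768 units) mapping a source-modality profile (p
#' features) to a target-modality profile (q features). The output layer
#' is also rectified, which guarantees non-negative generated expression
#' for any input.
#'
#' @param inputDim source feature count p.
#' @param outputDim target feature count q.
#' @param hiddenDims hidden layer widths, default `c(512, 768)`.
#' @param seed seed for the Kaiming-uniform parameter initialization.
#' @return A generator object (list with class `"Generator"`).
#' @export
makeGenerator <- function(inputDim, outputDim, hiddenDims = c(512L, 768L),
                          seed = 1L) {
  net <- mlp_new(inputDim, hiddenDims, outputDim,
                 output_activation = "relu", seed = seed)
  structure(list(net = net, inputDim = inputDim, outputDim = outputDim,
                 hiddenDims = hiddenDims, seed = as.integer(seed)),
            class = "Generator")
}

#' Construct the critic network
#'
#' A fully connected scorer with two rectifier hidden layers (default 256
#' and 128 units) and a single linear output unit producing an unbounded
#' score per sample; higher scores should indicate more realistic
#' profiles. The Lipschitz constraint of the Wasserstein formulation is
#' enforced by clipping every parameter to `[-clipValue, clipValue]`
#' after each optimizer step ([clipWeights()]).
#'
#' @param inputDim target feature count q.
#' @param hiddenDims hidden layer widths, default `c(256, 128)`.
#' @param clipValue half-width of the clip box, default 0.01.
#' @param seed seed for parameter initialization.
#' @return A critic object (list with class `"Critic"`).
#' @export
makeCritic <- function(inputDim, hiddenDims = c(256L, 128L),
                       clipValue = 0.01, seed = 1L) {
  if (clipValue <= 0) stopf("clipValue must be positive")
  net <- mlp_new(inputDim, hiddenDims, 1L,
                 output_activation = "identity", seed = seed)
  structure(list(net = net, inputDim = inputDim, hiddenDims = hiddenDims,
                 clipValue = clipValue, seed = as.integer(seed)),
            class = "Critic")
}

#' Generate target-modality profiles from source profiles
#'
#' Deterministic forward pass of the generator (no noise or dropout), so
#' repeated calls with the same parameters give identical output, and each
#' output row depends only on the matching input row.
#'
#' @param gen a generator from [makeGenerator()].
#' @param X numeric matrix (samples x p) of source profiles.
#' @return Non-negative matrix (samples x q) of generated target profiles.
#' @export
generateTarget <- function(gen, X) {
  stopifnot(inherits(gen, "Generator"))
  mlp_forward(gen$net, X)
}

#' Critic scores for a batch of profiles
#'
#' @param critic a critic from [makeCritic()].
#' @param Y numeric matrix (samples x q).
#' @return Numeric vector of unbounded scores, one per row.
#' @export
criticScore <- function(critic, Y) {
  stopifnot(inherits(critic, "Critic"))
  drop(mlp_forward(critic$net, Y))
}

#' Critic training loss
#'
#' `mean C(Y_fake) - mean C(Y_real)`: minimizing it drives real scores
#' above generated scores. Exactly antisymmetric in its two batch
#' arguments.
#'
#' @param critic a critic.
#' @param Y_real,Y_fake non-empty batches with the critic's feature count.
#' @return Scalar loss.
#' @export
criticLoss <- function(critic, Y_real, Y_fake) {
  if (NROW(Y_real) == 0L || NROW(Y_fake) == 0L)
    stopf("critic loss requires non-empty real and fake batches")
  mean(criticScore(critic, Y_fake)) - mean(criticScore(critic, Y_real))
}

#' Clip all critic parameters into the Lipschitz box
#'
#' Clamps every weight and bias of the critic to
#' `[-clipValue, clipValue]`; idempotent.
#'
#' @param critic a critic.
#' @return The clipped critic.
#' @export
clipWeights <- function(critic) {
  stopifnot(inherits(critic, "Critic"))
  cv <- critic$clipValue
  critic$net$W <- lapply(critic$net$W, function(w) pmin(pmax(w, -cv), cv))
  critic$net$b <- lapply(critic$net$b, function(x) pmin(pmax(x, -cv), cv))
  critic
}

critic_params_in_box <- function(critic) {
  cv <- critic$clipValue
  all(vapply(c(critic$net$W, critic$net$b),
             function(x) all(x >= -cv & x <= cv), logical(1L)))
}

#' Composite generator loss
#'
#' The generator minimizes
#' `-mean C(G(X)) + alpha * L_NMF + beta * MSE(Y_obs, G(X)[obs, ])`:
#' the adversarial and centroid-consistency terms use every batch row
#' (observed and missing alike), while the reconstruction term is
#' restricted to rows with observed target profiles. MSE is averaged over
#' elements so `alpha`/`beta` do not depend on batch size.
#'
#' @param critic a critic (ignored when `adversarial = FALSE`).
#' @param gen a generator.
#' @param X_batch source batch (b x p).
#' @param Y_obs observed target rows matching `obsIndex` (may have zero
#'   rows).
#' @param obsIndex integer rows of `X_batch` that have observed targets.
#' @param U_ref reference centroid matrix (required when `alpha > 0`).
#' @param alpha weight of the NMF centroid loss.
#' @param beta weight of the MSE reconstruction loss.
#' @param c cluster count for the batch decomposition.
#' @param seed seed for the batch decomposition.
#' @param adversarial include the critic term (disabled for the pure-MSE
#'   baseline mode).
#' @return List with elements `total`, `adversarial`, `nmf`, `mse`.
#' @export
generatorLoss <- function(critic, gen, X_batch, Y_obs = NULL,
                          obsIndex = integer(), U_ref = NULL,
                          alpha = 0, beta = 0, c = 10L, seed = 1L,
                          adversarial = TRUE) {
  stopifnot(inherits(gen, "Generator"))
  X_batch <- as.matrix(X_batch)
  Y_hat <- generateTarget(gen, X_batch)
  adv <- 0
  if (adversarial) adv <- -mean(criticScore(critic, Y_hat))
  nmf <- 0
  if (alpha > 0) {
    if (is.null(U_ref)) stopf("U_ref is required when alpha > 0")
    nmf <- nmf_loss_grad(U_ref, Y_hat, c = c, seed = seed, grad = FALSE)$loss
  }
  mse <- 0
  if (beta > 0) {
    if (length(obsIndex) == 0L) {
      warnf("no observed rows in batch; MSE term is 0")
    } else {
      mse <- mean((as.matrix(Y_obs) - Y_hat[obsIndex, , drop = FALSE])^2)
    }
  }
  list(total = adv + alpha * nmf + beta * mse,
       adversarial = adv, nmf = nmf, mse = mse)
}
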