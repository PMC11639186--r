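# Minimal fully-connected network machinery: seeded Kaiming-uniform
# initialization, cached forward pass, reverse-mode gradients, and an
# RMSprop optimizer. Kept deliberately small: both networks in this
# framework are two-hidden-layer rectifier MLPs on dense matrices, so a
# compact dedicated implementation is faster and easier to audit than a
# general autodiff graph.

mlp_new <- function(input_dim, hidden_dims, output_dim,
                    output_activation = c("relu", "identity"), seed = 1L) {
  output_activation <- match.arg(output_activation)
  dims <- c(input_dim, hidden_dims, output_dim)
  if (any(dims < 1L)) stopf("all layer dimensions must be positive")
  L <- length(dims) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  with_local_seed(seed, {
    for (l in seq_len(L)) {
      fan_in <- dims[l]
      lim <- sqrt(6 / fan_in)
      W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -lim, lim),
                       dims[l], dims[l + 1L])
      b[[l]] <- numeric(dims[l + 1L])
    }
  })
  list(W = W, b = b, dims = dims, L = L,
       output_activation = output_activation)
}

# Forward pass; with cache the per-layer activations are kept for backprop.
mlp_forward <- function(net, X, cache = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != net$dims[1L])
    stopf("input has %d features, network expects %d", ncol(X), net$dims[1L])
  A <- vector("list", net$L + 1L)
  A[[1L]] <- X
  for (l in seq_len(net$L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], "+")
    act <- if (l < net$L) "relu" else net$output_activation
    A[[l + 1L]] <- if (act == "relu") relu(Z) else Z
  }
  if (cache) list(out = A[[net$L + 1L]], A = A) else A[[net$L + 1L]]
}

# Reverse-mode gradients for a loss with d(loss)/d(output) = dOut.
# Returns parameter gradients and the gradient w.r.t. the input rows.
mlp_backward <- function(net, fw, dOut) {
  A <- fw$A
  dW <- vector("list", net$L)
  db <- vector("list", net$L)
  delta <- as.matrix(dOut)
  for (l in rev(seq_len(net$L))) {
    act <- if (l < net$L) "relu" else net$output_activation
    if (act == "relu") delta <- delta * (A[[l + 1L]] > 0)
    dW[[l]] <- crossprod(A[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) delta <- tcrossprod(delta, net$W[[l]])
    else delta <- tcrossprod(delta, net$W[[1L]])
  }
  list(dW = dW, db = db, dX = delta)
}

rmsprop_state <- function(net) {
  list(W = lapply(net$W, function(w) w * 0), b = lapply(net$b, function(x) x * 0))
}

rmsprop_step <- function(net, grads, state, lr, rho = 0.9, eps = 1e-8) {
  for (l in seq_len(net$L)) {
    state$W[[l]] <- rho * state$W[[l]] + (1 - rho) * grads$dW[[l]]^2
    state$b[[l]] <- rho * state$b[[l]] + (1 - rho) * grads$db[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * grads$dW[[l]] / (sqrt(state$W[[l]]) + eps)
    net$b[[l]] <- net$b[[l]] - lr * grads$db[[l]] / (sqrt(state$b[[l]]) + eps)
  }
  list(net = net, state = state)
}
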