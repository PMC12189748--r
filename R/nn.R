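# Minimal dense neural-network engine: leaky-ReLU MLPs with hand-written
# backprop, input gradients, exact gradient-penalty double-backprop (valid
# a.e. for piecewise-linear activations), and Adam. All randomness comes from
# R's RNG so a single set.seed() makes runs bit-reproducible.

lrelu <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)
lrelu_grad <- function(x, slope = 0.2) slope + (1 - slope) * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))
# stable log(1 + exp(x))
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

apply_act <- function(x, act, slope = 0.2) {
  switch(act,
         identity = x,
         lrelu = lrelu(x, slope),
         sigmoid = sigmoid(x),
         tanh = tanh(x),
         se_stop(paste("unknown activation", act)))
}
act_grad_from <- function(pre, out, act, slope = 0.2) {
  switch(act,
         identity = matrix(1, nrow(pre), ncol(pre)),
         lrelu = lrelu_grad(pre, slope),
         sigmoid = out * (1 - out),
         tanh = 1 - out^2,
         se_stop(paste("unknown activation", act)))
}

#' Construct a dense multi-layer perceptron
#'
#' Weights use He initialization for the leaky-ReLU hidden layers; biases
#' start at zero. Parameters are plain matrices in a named list so they can be
#' checksummed, serialized as text and updated by the shared Adam step.
#'
#' @param dims integer vector of layer widths, input first, output last.
#' @param act hidden activation (`"lrelu"`).
#' @param out_act output activation (`"identity"`, `"sigmoid"`, `"tanh"`).
#' @param slope leaky-ReLU negative slope.
#' @return object of class `synexpr_mlp` (list of `W`/`b` matrices plus spec).
#' @export
new_mlp <- function(dims, act = "lrelu", out_act = "identity", slope = 0.2) {
  K <- length(dims) - 1L
  if (K < 1) se_stop("`dims` needs at least input and output widths")
  W <- vector("list", K); b <- vector("list", K)
  for (k in seq_len(K)) {
    fan_in <- dims[k]
    sdv <- sqrt(2 / (fan_in * (1 + slope^2)))
    W[[k]] <- matrix(rnorm(fan_in * dims[k + 1], sd = sdv), fan_in, dims[k + 1])
    b[[k]] <- matrix(0, 1, dims[k + 1])
  }
  structure(list(W = W, b = b, dims = dims, act = act, out_act = out_act,
                 slope = slope),
            class = "synexpr_mlp")
}

#' Forward pass through an MLP
#' @param net a [new_mlp()] network.
#' @param X input matrix (rows = samples).
#' @param cache keep intermediate activations for [mlp_backward()].
#' @return list with `out` and (optionally) `cache`.
#' @export
mlp_forward <- function(net, X, cache = FALSE) {
  K <- length(net$W)
  if (ncol(X) != net$dims[1])
    se_stop(sprintf("input width %d does not match network input %d",
                    ncol(X), net$dims[1]), class = "synexpr_validation_error")
  H <- vector("list", K + 1L); A <- vector("list", K)
  H[[1]] <- X
  B <- nrow(X)
  for (k in seq_len(K)) {
    A[[k]] <- H[[k]] %*% net$W[[k]] + rep(net$b[[k]], each = B)
    actk <- if (k < K) net$act else net$out_act
    H[[k + 1]] <- apply_act(A[[k]], actk, net$slope)
  }
  if (cache) list(out = H[[K + 1]], cache = list(H = H, A = A))
  else list(out = H[[K + 1]])
}

#' Backward pass through an MLP
#' @param net the network.
#' @param cache cache from `mlp_forward(..., cache = TRUE)`.
#' @param dOut gradient of the loss with respect to the output.
#' @return list with `dW`, `db` (parameter gradients) and `dX` (input grad).
#' @export
mlp_backward <- function(net, cache, dOut) {
  K <- length(net$W)
  H <- cache$H; A <- cache$A
  dW <- vector("list", K); db <- vector("list", K)
  d <- dOut
  for (k in K:1) {
    actk <- if (k < K) net$act else net$out_act
    d <- d * act_grad_from(A[[k]], H[[k + 1]], actk, net$slope)
    dW[[k]] <- crossprod(H[[k]], d)
    db[[k]] <- matrix(colSums(d), 1)
    if (k > 1) d <- tcrossprod(d, net$W[[k]])
  }
  dX <- tcrossprod(d, net$W[[1]])
  list(dW = dW, db = db, dX = dX)
}

# Gradient of the scalar output with respect to the input, per sample.
# Requires a single linear output unit. Returns B x input_dim matrix.
mlp_input_grad <- function(net, X) {
  stopifnot(net$out_act == "identity", net$dims[length(net$dims)] == 1)
  fw <- mlp_forward(net, X, cache = TRUE)
  K <- length(net$W)
  A <- fw$cache$A
  B <- nrow(X)
  # T_k = d out / d a_k (per sample); start at the linear output layer
  Tk <- matrix(1, B, 1)
  if (K >= 2) for (k in seq(K, 2)) {
    Tk <- tcrossprod(Tk, net$W[[k]]) * lrelu_grad(A[[k - 1]], net$slope)
  }
  G <- tcrossprod(Tk, net$W[[1]])
  list(G = G, cache = fw$cache, score = fw$out)
}

# Gradient penalty lambda * mean((||grad_x D(xhat)||_2 - 1)^2) and its exact
# parameter gradients for a leaky-ReLU MLP critic with linear scalar output.
# Only the first `n_pen` input coordinates enter the norm (the expression
# block of a conditioned critic; the covariate embedding block is held fixed).
# Piecewise-linear activations have zero second derivative a.e., so the
# activation masks are constants of the differentiation and the double
# backprop is a pair of linear recursions.
mlp_gp_grads <- function(net, Xhat, lambda, n_pen = ncol(Xhat), eps = 1e-12) {
  K <- length(net$W)
  ig <- mlp_input_grad(net, Xhat)
  A <- ig$cache$A
  B <- nrow(Xhat)
  G <- ig$G
  Gp <- G[, seq_len(n_pen), drop = FALSE]
  norms <- sqrt(rowSums(Gp^2))
  penalty <- lambda * mean((norms - 1)^2)
  if (!is.finite(penalty))
    se_stop("non-finite gradient penalty", class = "synexpr_numeric_error")
  coef <- (2 * lambda / B) * (norms - 1) / pmax(norms, eps)
  U <- matrix(0, B, ncol(Xhat))
  U[, seq_len(n_pen)] <- Gp * coef
  # recompute T_k (d out / d a_k) top-down while walking up with R_k
  Tlist <- vector("list", K)   # T_k for k = 1..K-1 (per hidden layer)
  Tk <- matrix(1, B, 1)
  if (K >= 2) for (k in seq(K, 2)) {
    Tk <- tcrossprod(Tk, net$W[[k]]) * lrelu_grad(A[[k - 1]], net$slope)
    Tlist[[k - 1]] <- Tk
  }
  dW <- vector("list", K); db <- vector("list", K)
  Rk <- U
  for (k in seq_len(K)) {
    if (k < K) {
      dW[[k]] <- crossprod(Rk, Tlist[[k]])
      Rk <- (Rk %*% net$W[[k]]) * lrelu_grad(A[[k]], net$slope)
    } else {
      dW[[k]] <- matrix(colSums(Rk), ncol = 1)
    }
    db[[k]] <- matrix(0, 1, ncol(net$W[[k]]))
  }
  list(penalty = penalty, dW = dW, db = db, grad_norms = norms)
}

# ---- parameter-tree utilities (flat recursive lists of numeric arrays) ----

param_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- lapply(seq_along(t1), function(i)
      do.call(param_map, c(list(f), lapply(trees, `[[`, i))))
    names(out) <- names(t1)
    out
  } else {
    do.call(f, trees)
  }
}

zeros_like <- function(tree) param_map(function(x) x * 0, tree)

param_checksum <- function(tree) {
  vals <- unlist(tree, use.names = FALSE)
  # order-stable digest without external packages
  sum(vals * seq_along(vals) %% 97) + sum(vals^2)
}

#' Adam optimizer state and update
#'
#' Operates on arbitrary nested lists of numeric matrices (parameter trees),
#' so every model family in the package shares one optimizer.
#'
#' @param params parameter tree (nested list of matrices).
#' @return optimizer state; pass to [adam_step()].
#' @export
adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

#' @rdname adam_init
#' @param grads gradient tree of the same shape as `params`.
#' @param state state from [adam_init()].
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @return list with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.5,
                      beta2 = 0.9, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- param_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- param_map(function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}
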