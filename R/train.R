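# Adversarial training: WGAN-GP with optional graph generator and covariate
# conditioning, the vanilla GAN baseline, and the conditional VAE baseline.

#' Training configuration
#'
#' Defaults follow the published setup: 500 epochs, batch size 32, Adam with
#' alpha = 1e-4, beta1 = 0.5, beta2 = 0.9. Neither the critic/generator
#' update ratio nor the penalty strength is published; the package defaults
#' to 1:1 alternation (`n_critic = 1`) with `gp_lambda = 10`. With the
#' published learning rate and desk-scale epoch budgets, `n_critic = 5`
#' starves the generator (epochs x batches / 5 updates) and the
#' message-passing generator in particular fails to approach equilibrium;
#' the ratio remains configurable.
#'
#' @param epochs,batch_size,lr,beta1,beta2,n_critic,gp_lambda,seed numeric
#'   settings, see description.
#' @param checkpoint_every record a parameter checksum every this many epochs
#'   (0 disables).
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 500, batch_size = 32, lr = 1e-4,
                         beta1 = 0.5, beta2 = 0.9, n_critic = 1,
                         gp_lambda = 10, seed = 1, checkpoint_every = 0) {
  stopifnot(epochs >= 1, batch_size >= 2, lr > 0,
            beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            n_critic >= 1, gp_lambda >= 0)
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 beta1 = beta1, beta2 = beta2, n_critic = n_critic,
                 gp_lambda = gp_lambda, seed = seed,
                 checkpoint_every = checkpoint_every),
            class = "train_config")
}

#' WGAN-GP gradient penalty
#'
#' Interpolates `xhat = eps * x_real + (1 - eps) * x_fake` with one uniform
#' epsilon per sample and returns
#' `lambda * mean((||grad_xhat D(xhat)|| - 1)^2)`. With conditioning, the
#' covariate embedding block is concatenated but the gradient norm is taken
#' over the expression coordinates only.
#'
#' @param critic a [critic_network()] (leaky-ReLU MLP, linear scalar output).
#' @param x_real,x_fake batches of equal shape.
#' @param cemb conditioning batch or `NULL`.
#' @param lambda penalty strength.
#' @param return_grads also return parameter gradients (internal use).
#' @return the penalty value (scalar), with gradient details attached as
#'   attributes when `return_grads = TRUE`.
#' @export
gradient_penalty <- function(critic, x_real, x_fake, cemb = NULL,
                             lambda = 10, return_grads = FALSE) {
  stopifnot(all(dim(x_real) == dim(x_fake)))
  B <- nrow(x_real)
  eps <- runif(B)
  xhat <- x_real * eps + x_fake * (1 - eps)
  inp <- if (is.null(cemb) || !ncol(cemb)) xhat else cbind(xhat, cemb)
  res <- mlp_gp_grads(critic, inp, lambda, n_pen = ncol(xhat))
  if (!return_grads) return(res$penalty)
  structure(res$penalty, grads = list(dW = res$dW, db = res$db),
            grad_norms = res$grad_norms)
}

#' Wasserstein losses from critic scores
#'
#' Minimization form: critic loss `mean(D(fake)) - mean(D(real)) + penalty`;
#' generator loss `-mean(D(fake))`. The negative critic loss (ex-penalty) is
#' the critic's running estimate of the Wasserstein distance.
#'
#' @param real_scores,fake_scores numeric score vectors.
#' @param penalty gradient penalty value.
#' @return list with `critic_loss`, `generator_loss`, `wasserstein`.
#' @export
wgan_gp_losses <- function(real_scores, fake_scores, penalty = 0) {
  stopifnot(length(real_scores) >= 1, length(fake_scores) >= 1)
  w <- mean(real_scores) - mean(fake_scores)
  list(critic_loss = -w + penalty, generator_loss = -mean(fake_scores),
       wasserstein = w)
}

# epoch batching: shuffles, drops a trailing batch only when it has 1 sample
epoch_batches <- function(n, batch_size) {
  ord <- sample.int(n)
  starts <- seq(1, n, by = batch_size)
  batches <- lapply(starts, function(s) ord[s:min(s + batch_size - 1, n)])
  if (length(batches) > 1 && length(batches[[length(batches)]]) < 2)
    batches[[length(batches)]] <- NULL
  batches
}

#' Train a (graph-informed) conditional WGAN-GP
#'
#' Alternates `n_critic` critic updates per generator update over shuffled
#' minibatches. The generator is either graph-based (`spec$layer_family` in
#' `"graphconv"`/`"h2gcn"`, message passing over `graph`) or the fully
#' connected baseline (`"mlp"`, `graph` ignored). Covariate embedding tables
#' are owned by the generator and receive gradients through both networks;
#' the critic treats the embedded condition as a constant during its own
#' update. Fully reproducible given `config$seed`.
#'
#' @param X normalized [expression_matrix()] (training space).
#' @param C a `cov_table` aligned to `X`, or `NULL` for unconditional models.
#' @param graph a [gene_graph()] whose `gene_ids` match `X` (or `NULL`).
#' @param spec a [generator_spec()].
#' @param config a [train_config()].
#' @param emb_rule embedding dimension rule.
#' @param verbose print a progress line every 50 epochs.
#' @return object of class `synexpr_gan` with parameters, specs and a
#'   per-epoch `history` tibble (critic loss, generator loss, penalty,
#'   Wasserstein estimate).
#' @export
train_wgan_gp <- function(X, C = NULL, graph = NULL, spec = NULL,
                          config = train_config(), emb_rule = "paper_literal",
                          verbose = FALSE) {
  v <- as_expr_values(X)
  n <- ncol(v); nobs <- nrow(v)
  if (is.null(spec))
    spec <- generator_spec(n, layer_family = if (is.null(graph)) "mlp"
                           else "graphconv")
  if (spec$n_genes != n) se_stop("spec/gene-count mismatch",
                                 class = "synexpr_validation_error")
  if (!is.null(graph)) {
    if (!identical(graph$gene_ids, colnames(v)))
      se_stop("graph gene order must match the expression matrix",
              class = "synexpr_validation_error")
  } else if (spec$layer_family != "mlp") {
    se_stop("graph-based layer families need a `graph`")
  }
  set.seed(config$seed)
  vocabs <- if (is.null(C)) list() else vocabularies(C)
  emb <- covariate_embedding(vocabs, rule = emb_rule)
  codes <- if (is.null(C)) matrix(integer(), nobs, 0) else covariate_codes(C)
  use_graph_gen <- spec$layer_family != "mlp"
  if (use_graph_gen) {
    gen_params <- gen_init(spec, emb)
    ops <- gen_operators(spec, graph)
    bop_cache <- list()
  } else {
    gnet <- new_mlp(c(spec$latent_dim + emb$m, spec$hidden, n),
                    out_act = spec$output_activation, slope = spec$slope)
    gen_params <- list(net = list(W = gnet$W, b = gnet$b), emb = emb$tables)
  }
  critic <- critic_network(n, emb$m, slope = spec$slope)
  crit_params <- list(W = critic$W, b = critic$b)
  g_state <- adam_init(gen_params)
  c_state <- adam_init(crit_params)
  d <- spec$latent_dim
  hist <- vector("list", config$epochs)
  checkpoints <- list()

  sync_critic <- function() { critic$W <<- crit_params$W; critic$b <<- crit_params$b }
  gen_fwd <- function(Z, Cemb, cache = FALSE, B = nrow(Z)) {
    if (use_graph_gen) {
      key <- as.character(B)
      if (is.null(bop_cache[[key]]))
        bop_cache[[key]] <<- batch_ops(ops, B)
      gen_forward(gen_params, spec, bop_cache[[key]], Z, Cemb, cache = cache)
    } else {
      net <- gnet; net$W <- gen_params$net$W; net$b <- gen_params$net$b
      mlp_forward(net, cbind(Z, Cemb), cache = cache)
    }
  }

  for (ep in seq_len(config$epochs)) {
    batches <- epoch_batches(nobs, config$batch_size)
    ep_cl <- ep_gl <- ep_gp <- ep_w <- c()
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      B <- length(idx)
      emb$tables <- gen_params$emb
      Cemb <- embed_covariates(emb, codes[idx, , drop = FALSE])
      # ---- critic update ----
      Z <- matrix(rnorm(B * d), B, d)
      x_fake <- gen_fwd(Z, Cemb, cache = FALSE, B = B)$out
      x_real <- v[idx, , drop = FALSE]
      inp_real <- if (emb$m) cbind(x_real, Cemb) else x_real
      inp_fake <- if (emb$m) cbind(x_fake, Cemb) else x_fake
      fr <- mlp_forward(critic, inp_real, cache = TRUE)
      ff <- mlp_forward(critic, inp_fake, cache = TRUE)
      gp <- gradient_penalty(critic, x_real, x_fake,
                             if (emb$m) Cemb else NULL,
                             lambda = config$gp_lambda, return_grads = TRUE)
      losses <- wgan_gp_losses(drop(fr$out), drop(ff$out), as.numeric(gp))
      if (!is.finite(losses$critic_loss))
        se_stop(sprintf("NaN critic loss at epoch %d", ep),
                class = "synexpr_numeric_error")
      br <- mlp_backward(critic, fr$cache,
                         matrix(-1 / B, B, 1))
      bf <- mlp_backward(critic, ff$cache, matrix(1 / B, B, 1))
      gpg <- attr(gp, "grads")
      dW <- param_map(function(a, b2, c2) a + b2 + c2,
                      br$dW, bf$dW, gpg$dW)
      db <- param_map(function(a, b2, c2) a + b2 + c2,
                      br$db, bf$db, gpg$db)
      upd <- adam_step(crit_params, list(W = dW, b = db), c_state,
                       lr = config$lr, beta1 = config$beta1,
                       beta2 = config$beta2)
      crit_params <- upd$params; c_state <- upd$state
      sync_critic()
      ep_cl <- c(ep_cl, losses$critic_loss)
      ep_gp <- c(ep_gp, as.numeric(gp))
      ep_w <- c(ep_w, losses$wasserstein)
      # ---- generator update every n_critic batches ----
      if (bi %% config$n_critic == 0 || bi == length(batches)) {
        Z <- matrix(rnorm(B * d), B, d)
        gfw <- gen_fwd(Z, Cemb, cache = TRUE, B = B)
        inp <- if (emb$m) cbind(gfw$out, Cemb) else gfw$out
        fs <- mlp_forward(critic, inp, cache = TRUE)
        gl <- -mean(fs$out)
        if (!is.finite(gl))
          se_stop(sprintf("NaN generator loss at epoch %d", ep),
                  class = "synexpr_numeric_error")
        bs <- mlp_backward(critic, fs$cache, matrix(-1 / B, B, 1))
        dX <- bs$dX[, seq_len(n), drop = FALSE]
        dCemb_critic <- if (emb$m)
          bs$dX[, n + seq_len(emb$m), drop = FALSE] else NULL
        if (use_graph_gen) {
          bw <- gen_backward(gen_params, spec,
                             bop_cache[[as.character(B)]], gfw$cache, dX,
                             spec$latent_dim)
          ggrads <- bw$grads
          dCemb <- bw$dCemb
        } else {
          net <- gnet; net$W <- gen_params$net$W; net$b <- gen_params$net$b
          bw <- mlp_backward(net, gfw$cache, dX)
          ggrads <- list(net = list(W = bw$dW, b = bw$db))
          dCemb <- if (emb$m)
            bw$dX[, spec$latent_dim + seq_len(emb$m), drop = FALSE] else NULL
        }
        if (emb$m) {
          dC <- dCemb + dCemb_critic
          ggrads$emb <- embed_backward(emb, codes[idx, , drop = FALSE], dC)
        } else {
          ggrads$emb <- list()
        }
        # align gradient tree shape with the parameter tree
        ggrads <- ggrads[names(gen_params)]
        upd <- adam_step(gen_params, ggrads, g_state, lr = config$lr,
                         beta1 = config$beta1, beta2 = config$beta2)
        gen_params <- upd$params; g_state <- upd$state
        ep_gl <- c(ep_gl, gl)
      }
    }
    hist[[ep]] <- tibble::tibble(
      epoch = ep, critic_loss = mean(ep_cl),
      generator_loss = mean(ep_gl), penalty = mean(ep_gp),
      wasserstein = mean(ep_w))
    if (config$checkpoint_every > 0 && ep %% config$checkpoint_every == 0)
      checkpoints[[length(checkpoints) + 1]] <-
        list(epoch = ep, checksum = param_checksum(gen_params))
    if (verbose && ep %% 50 == 0)
      message(sprintf("epoch %d: critic %.4f gen %.4f W %.4f", ep,
                      mean(ep_cl), mean(ep_gl), mean(ep_w)))
  }
  emb$tables <- gen_params$emb
  structure(list(kind = if (use_graph_gen) "graph_wgan_gp" else "wgan_gp",
                 spec = spec, config = config, gen_params = gen_params,
                 gnet = if (use_graph_gen) NULL else gnet,
                 critic = critic, emb = emb, graph = graph,
                 gene_ids = colnames(v),
                 covariates = if (is.null(C)) NULL else
                   C[covariate_names(C)],
                 history = dplyr::bind_rows(hist),
                 checkpoints = checkpoints,
                 checksum = param_checksum(gen_params)),
            class = c("synexpr_gan", "synexpr_fit"))
}

#' @method print synexpr_gan
#' @export
print.synexpr_gan <- function(x, ...) {
  cat(sprintf("<synexpr_gan> %s generator, %d genes, %d epochs\n",
              x$spec$layer_family, length(x$gene_ids), nrow(x$history)))
  invisible(x)
}

#' Sample synthetic expression from a trained model
#'
#' Draws latent vectors and conditions either on a supplied covariate table
#' or by resampling rows of the training covariates (preserving their joint
#' empirical distribution, including class imbalance).
#'
#' @param fit a fitted model from [train_wgan_gp()], [train_baseline_gan()]
#'   or [train_cvae()].
#' @param n number of samples (ignored when `covariates` is given).
#' @param covariates optional `cov_table` providing the conditions.
#' @param seed RNG seed.
#' @return list with `X` (an [expression_matrix()] in the training space) and
#'   `C` (the covariate table used, or `NULL`).
#' @export
generate_expression <- function(fit, n = 100, covariates = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(covariates) && !is.null(fit$covariates)) {
    idx <- sample.int(nrow(fit$covariates), n, replace = TRUE)
    covariates <- fit$covariates[idx, , drop = FALSE]
    covariates$sample_id <- paste0("syn", seq_len(n))
    covariates <- covariate_table(covariates)
  }
  if (!is.null(covariates)) n <- nrow(covariates)
  emb <- fit$emb
  Cemb <- if (is.null(covariates) || !emb$m) matrix(0, n, 0)
  else embed_covariates(emb, codes_for_embedding(emb, covariates))
  d <- if (!is.null(fit$spec)) fit$spec$latent_dim else fit$latent_dim
  Z <- matrix(rnorm(n * d), n, d)
  out <- switch(fit$kind,
    graph_wgan_gp = {
      ops <- gen_operators(fit$spec, fit$graph)
      gen_forward(fit$gen_params, fit$spec, batch_ops(ops, n), Z, Cemb)$out
    },
    wgan_gp = ,
    gan = {
      net <- fit$gnet
      net$W <- fit$gen_params$net$W; net$b <- fit$gen_params$net$b
      mlp_forward(net, cbind(Z, Cemb))$out
    },
    cvae = {
      net <- fit$decoder
      mlp_forward(net, cbind(Z, Cemb))$out
    },
    se_stop("unknown model kind"))
  colnames(out) <- fit$gene_ids
  rownames(out) <- paste0("syn", seq_len(n))
  space <- if (!is.null(fit$spec) && fit$spec$output_activation == "sigmoid")
    "minmax01" else if (is.null(fit$spec)) fit$space_tag else "log2_zscore"
  X <- expression_matrix(out, space = space)
  list(X = X, C = covariates)
}

#' Train the vanilla GAN baseline
#'
#' Fully connected generator and discriminator (two hidden layers of 256
#' leaky-ReLU units). Uses the original saturating objective
#' `min_G max_D E[log D(x)] + E[log(1 - D(G(z)))]`, evaluated through
#' numerically stable softplus forms so scores of large magnitude stay
#' finite. This baseline is expected to mode-collapse on multimodal data.
#'
#' @inheritParams train_wgan_gp
#' @param latent_dim latent dimension.
#' @param output_activation generator output activation.
#' @export
train_baseline_gan <- function(X, C = NULL, config = train_config(),
                               latent_dim = 64,
                               output_activation = "sigmoid",
                               emb_rule = "paper_literal") {
  v <- as_expr_values(X)
  n <- ncol(v); nobs <- nrow(v)
  set.seed(config$seed)
  vocabs <- if (is.null(C)) list() else vocabularies(C)
  emb <- covariate_embedding(vocabs, rule = emb_rule)
  codes <- if (is.null(C)) matrix(integer(), nobs, 0) else covariate_codes(C)
  gnet <- new_mlp(c(latent_dim + emb$m, 256, 256, n),
                  out_act = output_activation)
  dnet <- new_mlp(c(n + emb$m, 256, 256, 1)) # linear score; sigmoid in loss
  gen_params <- list(net = list(W = gnet$W, b = gnet$b), emb = emb$tables)
  dis_params <- list(W = dnet$W, b = dnet$b)
  g_state <- adam_init(gen_params); d_state <- adam_init(dis_params)
  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    batches <- epoch_batches(nobs, config$batch_size)
    ep_dl <- ep_gl <- c()
    for (idx in batches) {
      B <- length(idx)
      emb$tables <- gen_params$emb
      Cemb <- embed_covariates(emb, codes[idx, , drop = FALSE])
      Z <- matrix(rnorm(B * latent_dim), B, latent_dim)
      gnet$W <- gen_params$net$W; gnet$b <- gen_params$net$b
      gfw <- mlp_forward(gnet, cbind(Z, Cemb), cache = TRUE)
      x_fake <- gfw$out
      x_real <- v[idx, , drop = FALSE]
      dnet$W <- dis_params$W; dnet$b <- dis_params$b
      fr <- mlp_forward(dnet, if (emb$m) cbind(x_real, Cemb) else x_real,
                        cache = TRUE)
      ff <- mlp_forward(dnet, if (emb$m) cbind(x_fake, Cemb) else x_fake,
                        cache = TRUE)
      sr <- drop(fr$out); sf <- drop(ff$out)
      # discriminator: minimize softplus(-s_real) + softplus(s_fake)
      dl <- mean(softplus(-sr)) + mean(softplus(sf))
      dr <- matrix(-sigmoid(-sr) / B, ncol = 1)
      df <- matrix(sigmoid(sf) / B, ncol = 1)
      br <- mlp_backward(dnet, fr$cache, dr)
      bf <- mlp_backward(dnet, ff$cache, df)
      upd <- adam_step(dis_params,
                       list(W = param_map(`+`, br$dW, bf$dW),
                            b = param_map(`+`, br$db, bf$db)),
                       d_state, lr = config$lr, beta1 = config$beta1,
                       beta2 = config$beta2)
      dis_params <- upd$params; d_state <- upd$state
      # generator: minimize log(1 - D(G(z))) = -softplus(s_fake)
      dnet$W <- dis_params$W; dnet$b <- dis_params$b
      ff2 <- mlp_forward(dnet, if (emb$m) cbind(x_fake, Cemb) else x_fake,
                         cache = TRUE)
      sf2 <- drop(ff2$out)
      gl <- mean(-softplus(sf2))
      dsf <- matrix(-sigmoid(sf2) / B, ncol = 1)
      bd <- mlp_backward(dnet, ff2$cache, dsf)
      dX <- bd$dX[, seq_len(n), drop = FALSE]
      bg <- mlp_backward(gnet, gfw$cache, dX)
      ggrads <- list(net = list(W = bg$dW, b = bg$db))
      if (emb$m) {
        dCemb <- bg$dX[, latent_dim + seq_len(emb$m), drop = FALSE] +
          bd$dX[, n + seq_len(emb$m), drop = FALSE]
        ggrads$emb <- embed_backward(emb, codes[idx, , drop = FALSE], dCemb)
      } else ggrads$emb <- list()
      ggrads <- ggrads[names(gen_params)]
      upd <- adam_step(gen_params, ggrads, g_state, lr = config$lr,
                       beta1 = config$beta1, beta2 = config$beta2)
      gen_params <- upd$params; g_state <- upd$state
      ep_dl <- c(ep_dl, dl); ep_gl <- c(ep_gl, gl)
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, critic_loss = mean(ep_dl),
                                 generator_loss = mean(ep_gl),
                                 penalty = 0, wasserstein = NA_real_)
  }
  emb$tables <- gen_params$emb
  structure(list(kind = "gan", gen_params = gen_params, gnet = gnet,
                 emb = emb, latent_dim = latent_dim, gene_ids = colnames(v),
                 covariates = if (is.null(C)) NULL else C[covariate_names(C)],
                 space_tag = if (output_activation == "sigmoid") "minmax01"
                 else "log2_zscore",
                 spec = NULL, config = config,
                 history = dplyr::bind_rows(hist),
                 checksum = param_checksum(gen_params)),
            class = c("synexpr_gan", "synexpr_fit"))
}

#' Train the conditional VAE baseline
#'
#' Encoder and decoder with a single hidden layer of 256 units and a
#' 64-dimensional Gaussian latent space, trained on the negative evidence
#' lower bound: per-sample squared reconstruction error summed over genes
#' (times `recon_weight`, the inverse observation-noise scale of the implied
#' Gaussian likelihood) plus the closed-form KL divergence to the standard
#' normal prior. With few genes the KL term dominates a unit-weight
#' reconstruction and the posterior collapses; raise `recon_weight` (to
#' roughly 1 / (2 * noise variance)) when training on small panels.
#'
#' @inheritParams train_baseline_gan
#' @param recon_weight multiplier on the squared reconstruction error.
#' @export
train_cvae <- function(X, C = NULL, config = train_config(),
                       output_activation = "sigmoid",
                       emb_rule = "paper_literal", recon_weight = 1) {
  v <- as_expr_values(X)
  n <- ncol(v); nobs <- nrow(v)
  set.seed(config$seed)
  vocabs <- if (is.null(C)) list() else vocabularies(C)
  emb <- covariate_embedding(vocabs, rule = emb_rule)
  codes <- if (is.null(C)) matrix(integer(), nobs, 0) else covariate_codes(C)
  latent_dim <- 64
  bundle <- build_baseline("cvae", n, emb$m,
                           output_activation = output_activation)
  enc <- bundle$encoder; dec <- bundle$decoder
  params <- list(enc = list(W = enc$W, b = enc$b),
                 dec = list(W = dec$W, b = dec$b), emb = emb$tables)
  state <- adam_init(params)
  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    batches <- epoch_batches(nobs, config$batch_size)
    ep_l <- ep_r <- ep_k <- c()
    for (idx in batches) {
      B <- length(idx)
      emb$tables <- params$emb
      Cemb <- embed_covariates(emb, codes[idx, , drop = FALSE])
      x <- v[idx, , drop = FALSE]
      enc$W <- params$enc$W; enc$b <- params$enc$b
      dec$W <- params$dec$W; dec$b <- params$dec$b
      ef <- mlp_forward(enc, if (emb$m) cbind(x, Cemb) else x, cache = TRUE)
      mu <- ef$out[, seq_len(latent_dim), drop = FALSE]
      logvar <- ef$out[, latent_dim + seq_len(latent_dim), drop = FALSE]
      logvar <- pmin(pmax(logvar, -10), 10)
      epsm <- matrix(rnorm(B * latent_dim), B, latent_dim)
      z <- mu + exp(0.5 * logvar) * epsm
      dfw <- mlp_forward(dec, cbind(z, Cemb), cache = TRUE)
      xhat <- dfw$out
      recon <- mean(rowSums((xhat - x)^2))
      kl <- mean(rowSums(-0.5 * (1 + logvar - mu^2 - exp(logvar))))
      loss <- recon_weight * recon + kl
      dXhat <- recon_weight * 2 * (xhat - x) / B
      bd <- mlp_backward(dec, dfw$cache, dXhat)
      dz <- bd$dX[, seq_len(latent_dim), drop = FALSE]
      dmu <- dz + mu / B
      dlogvar <- dz * epsm * 0.5 * exp(0.5 * logvar) +
        (-0.5 * (1 - exp(logvar))) / B
      be <- mlp_backward(enc, ef$cache, cbind(dmu, dlogvar))
      grads <- list(enc = list(W = be$dW, b = be$db),
                    dec = list(W = bd$dW, b = bd$db))
      if (emb$m) {
        dCemb <- be$dX[, n + seq_len(emb$m), drop = FALSE] +
          bd$dX[, latent_dim + seq_len(emb$m), drop = FALSE]
        grads$emb <- embed_backward(emb, codes[idx, , drop = FALSE], dCemb)
      } else grads$emb <- list()
      grads <- grads[names(params)]
      upd <- adam_step(params, grads, state, lr = config$lr,
                       beta1 = config$beta1, beta2 = config$beta2)
      params <- upd$params; state <- upd$state
      ep_l <- c(ep_l, loss); ep_r <- c(ep_r, recon); ep_k <- c(ep_k, kl)
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, loss = mean(ep_l),
                                 reconstruction = mean(ep_r), kl = mean(ep_k))
  }
  emb$tables <- params$emb
  dec$W <- params$dec$W; dec$b <- params$dec$b
  enc$W <- params$enc$W; enc$b <- params$enc$b
  structure(list(kind = "cvae", encoder = enc, decoder = dec, emb = emb,
                 latent_dim = latent_dim, gene_ids = colnames(v),
                 covariates = if (is.null(C)) NULL else C[covariate_names(C)],
                 space_tag = if (output_activation == "sigmoid") "minmax01"
                 else "log2_zscore",
                 spec = NULL, config = config,
                 history = dplyr::bind_rows(hist),
                 checksum = param_checksum(params)),
            class = c("synexpr_cvae", "synexpr_fit"))
}

#' @method print synexpr_cvae
#' @export
print.synexpr_cvae <- function(x, ...) {
  cat(sprintf("<synexpr_cvae> %d genes, %d epochs, final ELBO loss %.3f\n",
              length(x$gene_ids), nrow(x$history),
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' Closed-form KL divergence of a diagonal Gaussian posterior to N(0, I)
#'
#' `KL = -0.5 * sum(1 + logvar - mu^2 - exp(logvar))`, per sample.
#' @param mu,logvar posterior mean and log-variance matrices (rows = samples).
#' @return numeric vector, one KL value per row.
#' @export
gaussian_kl <- function(mu, logvar) {
  rowSums(-0.5 * (1 + logvar - mu^2 - exp(logvar)))
}
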