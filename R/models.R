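# Covariate embeddings, the graph-based generator (1-hop GraphConv family and
# the heterophily-aware 1-hop/2-hop family), the MLP critic, and the fully
# connected baselines. Forward and backward passes are written out by hand;
# the backward passes are finite-difference-tested.

#' Embedding dimension rule for a categorical covariate
#'
#' `paper_literal` applies the printed rule floor(l + 1); `sqrt_plus_one`
#' applies floor(sqrt(l)) + 1, the usual vocabulary-compressing choice. The
#' literal rule makes each embedding one unit wider than its vocabulary; it is
#' the default for fidelity to the published configuration.
#'
#' @param l vocabulary size (>= 1).
#' @param rule `"paper_literal"` or `"sqrt_plus_one"`.
#' @return integer embedding dimension.
#' @export
embedding_dim <- function(l, rule = c("paper_literal", "sqrt_plus_one")) {
  rule <- match.arg(rule)
  if (any(l < 1)) se_stop("vocabulary size must be >= 1",
                          class = "synexpr_validation_error")
  if (rule == "paper_literal") as.integer(floor(l + 1))
  else as.integer(floor(sqrt(l)) + 1)
}

#' Covariate embedding specification
#'
#' One learned table per covariate, of shape vocabulary-size x embedding-dim;
#' the conditioning vector is the concatenation of the looked-up rows, total
#' width `m = sum(d_j)`.
#'
#' @param vocabs named list of per-covariate category vectors (from
#'   [vocabularies()]).
#' @param rule embedding dimension rule, see [embedding_dim()].
#' @param init_sd standard deviation of the random initialization.
#' @return object of class `cov_embedding` with `tables` (parameter tree),
#'   `dims`, and total width `m`.
#' @export
covariate_embedding <- function(vocabs, rule = "paper_literal",
                                init_sd = 0.1) {
  if (!length(vocabs)) {
    return(structure(list(tables = list(), vocabs = list(),
                          dims = integer(), m = 0L, rule = rule),
                     class = "cov_embedding"))
  }
  dims <- vapply(vocabs, function(v) embedding_dim(length(v), rule),
                 integer(1))
  tables <- lapply(seq_along(vocabs), function(j)
    matrix(rnorm(length(vocabs[[j]]) * dims[j], sd = init_sd),
           length(vocabs[[j]]), dims[j],
           dimnames = list(vocabs[[j]], NULL)))
  names(tables) <- names(vocabs)
  structure(list(tables = tables, vocabs = vocabs, dims = dims,
                 m = sum(dims), rule = rule),
            class = "cov_embedding")
}

#' Embed covariate categories
#'
#' @param emb a [covariate_embedding()].
#' @param codes integer matrix (samples x covariates) of 1-based category
#'   codes aligned with the embedding vocabularies, or a `cov_table`.
#' @return matrix of shape samples x m.
#' @export
embed_covariates <- function(emb, codes) {
  if (inherits(codes, "cov_table")) codes <- covariate_codes(codes)
  if (!length(emb$tables)) return(matrix(0, nrow(codes), 0))
  if (ncol(codes) != length(emb$tables))
    se_stop("covariate count does not match the embedding spec",
            class = "synexpr_validation_error")
  for (j in seq_along(emb$tables)) {
    lj <- nrow(emb$tables[[j]])
    if (any(codes[, j] < 1 | codes[, j] > lj))
      se_stop(sprintf("out-of-vocabulary category code for covariate '%s'",
                      names(emb$tables)[j]),
              class = "synexpr_validation_error")
  }
  do.call(cbind, lapply(seq_along(emb$tables), function(j)
    emb$tables[[j]][codes[, j], , drop = FALSE]))
}

# gradient wrt embedding tables given dCemb (B x m)
embed_backward <- function(emb, codes, dCemb) {
  grads <- vector("list", length(emb$tables))
  names(grads) <- names(emb$tables)
  off <- 0L
  for (j in seq_along(emb$tables)) {
    dj <- emb$dims[j]
    slice <- dCemb[, off + seq_len(dj), drop = FALSE]
    g <- matrix(0, nrow(emb$tables[[j]]), dj)
    agg <- rowsum(slice, group = codes[, j])
    g[as.integer(rownames(agg)), ] <- agg
    grads[[j]] <- g
    off <- off + dj
  }
  grads
}

# map categories of a cov_table into codes matching an embedding's vocabs
codes_for_embedding <- function(emb, ct) {
  covs <- names(emb$vocabs)
  missing <- setdiff(covs, covariate_names(ct))
  if (length(missing))
    se_stop(paste0("covariates absent from table: ",
                   paste(missing, collapse = ", ")),
            class = "synexpr_validation_error")
  m <- vapply(covs, function(v) {
    idx <- match(as.character(ct[[v]]), emb$vocabs[[v]])
    if (anyNA(idx))
      se_stop(sprintf("out-of-vocabulary category in covariate '%s'", v),
              class = "synexpr_validation_error")
    idx
  }, integer(nrow(ct)))
  matrix(m, nrow = nrow(ct), dimnames = list(NULL, covs))
}

#' Generator architecture specification
#'
#' The generator maps `v = [z, c]` through a dense layer assigning one initial
#' scalar per gene node (`h0 = sigma(W_I v + b_I)`), then refines node
#' features with `n_mp_layers` rounds of message passing over the prior gene
#' graph. Two layer families are available:
#' * `graphconv` — 1-hop aggregation weighted by the adjacency entries, with a
#'   learned self term: `h_i' = sigma(h_i W1 + sum_j A[j,i] h_j W2)`.
#' * `h2gcn` — heterophily-aware: separate degree-normalized 1-hop and 2-hop
#'   aggregates, concatenated (no self mixing), with a final readout that
#'   concatenates all intermediate representations and projects each node to
#'   a scalar.
#' `mlp` gives the fully connected graph-free generator used by the baselines.
#'
#' @param n_genes number of gene nodes.
#' @param layer_family `"graphconv"`, `"h2gcn"` or `"mlp"`.
#' @param latent_dim dimension d of the Gaussian latent z (default 64).
#' @param n_mp_layers rounds of message passing L (default 4).
#' @param node_dim hidden node-feature width p for graphconv (default 8).
#' @param output_activation `"sigmoid"` for data in \[0,1\], `"identity"` for
#'   z-scored data.
#' @param aggregator 1-hop neighborhood aggregation: `"sum"` (weighted sum,
#'   the default — the adjacency entry already scales each contribution) or
#'   `"mean"` (weighted average over the in-neighborhood).
#' @param abs_weights use |A| instead of signed adjacency weights in message
#'   passing.
#' @param normalization h2gcn degree normalization (`"sym_sqrt_degree"` or
#'   the literal `"product_degree"`).
#' @param hidden hidden widths for the `mlp` family.
#' @param slope leaky-ReLU slope for sigma.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n_genes,
                           layer_family = c("graphconv", "h2gcn", "mlp"),
                           latent_dim = 64, n_mp_layers = 4, node_dim = 8,
                           output_activation = c("sigmoid", "identity"),
                           aggregator = c("sum", "mean"),
                           abs_weights = FALSE,
                           normalization = "sym_sqrt_degree",
                           hidden = c(256, 256), slope = 0.2) {
  layer_family <- match.arg(layer_family)
  output_activation <- match.arg(output_activation)
  aggregator <- match.arg(aggregator)
  if (n_mp_layers < 1) se_stop("`n_mp_layers` must be >= 1")
  structure(list(n_genes = n_genes, layer_family = layer_family,
                 latent_dim = latent_dim, n_mp_layers = n_mp_layers,
                 node_dim = node_dim, output_activation = output_activation,
                 aggregator = aggregator,
                 abs_weights = abs_weights, normalization = normalization,
                 hidden = hidden, slope = slope),
            class = "generator_spec")
}

# per-layer feature widths for each family
gen_widths <- function(spec) {
  L <- spec$n_mp_layers
  if (spec$layer_family == "graphconv") {
    if (L == 1) list(inw = 1, outw = 1)
    else list(inw = c(1, rep(spec$node_dim, L - 1)),
              outw = c(rep(spec$node_dim, L - 1), 1))
  } else {
    w <- 2^(0:(L - 1)) # widths double through concatenation, starting at 1
    list(inw = w, outw = 2 * w)
  }
}

# initialize generator parameters (a parameter tree)
gen_init <- function(spec, emb, init_sd = NULL) {
  d <- spec$latent_dim; m <- emb$m; n <- spec$n_genes
  params <- list()
  params$WI <- matrix(rnorm((d + m) * n, sd = sqrt(2 / ((d + m) * 1.04))),
                      d + m, n)
  params$bI <- matrix(0, 1, n)
  wd <- gen_widths(spec)
  layers <- vector("list", spec$n_mp_layers)
  for (t in seq_len(spec$n_mp_layers)) {
    inw <- wd$inw[min(t, length(wd$inw))]
    outw <- if (spec$layer_family == "graphconv")
      wd$outw[min(t, length(wd$outw))] else wd$inw[t]
    # He init for the leaky-ReLU channels
    sdv <- sqrt(2 / (max(inw, 1) * (1 + spec$slope^2)))
    layers[[t]] <- list(W1 = matrix(rnorm(inw * outw, sd = sdv), inw, outw),
                        W2 = matrix(rnorm(inw * outw, sd = sdv), inw, outw))
    if (spec$layer_family == "graphconv")
      # the reference GraphConv implementation carries a per-channel bias
      layers[[t]]$b <- matrix(0, 1, outw)
  }
  params$layers <- layers
  if (spec$layer_family == "h2gcn") {
    total <- 1 + sum(wd$outw) # h0 plus every intermediate representation
    params$Wc <- matrix(rnorm(total, sd = sqrt(1 / total)), total, 1)
  }
  params$emb <- emb$tables
  params
}

# operators needed by the generator for batch size B: block-diagonal
# I_B (x) S so a whole batch of node-feature matrices multiplies at once
gen_operators <- function(spec, graph) {
  if (spec$layer_family == "mlp" || is.null(graph)) return(list())
  if (spec$layer_family == "graphconv") {
    S <- graph_operator(graph, abs_weights = spec$abs_weights)
    if (identical(spec$aggregator, "mean")) {
      deg <- Matrix::rowSums(S != 0)
      S <- S / pmax(deg, 1)
    }
    list(S1 = S)
  } else {
    op <- h2gcn_operators(graph, abs_weights = spec$abs_weights,
                          normalization = spec$normalization)
    list(S1 = op$S1, S2 = op$S2)
  }
}

batch_ops <- function(ops, B) {
  lapply(ops, function(S) {
    K <- Matrix::bdiag(rep(list(S), B))
    list(K = K, Kt = Matrix::t(K))
  })
}

# B x n matrix -> (B*n) x 1 column (sample-major blocks) and back
bn_fold <- function(M) matrix(as.vector(t(M)), ncol = 1)
bn_unfold <- function(v, B, n) matrix(as.vector(v), nrow = B, ncol = n,
                                      byrow = TRUE)

# ---- graph generator forward/backward ----

gen_forward <- function(params, spec, bops, Z, Cemb, cache = FALSE) {
  B <- nrow(Z); n <- spec$n_genes
  V <- cbind(Z, Cemb)
  A0 <- V %*% params$WI + rep(params$bI, each = B)
  H0m <- lrelu(A0, spec$slope)
  if (spec$layer_family == "mlp")
    se_stop("mlp family is handled by the baseline generator")
  H <- bn_fold(H0m) # (B*n) x 1
  caches <- list()
  L <- spec$n_mp_layers
  intermediates <- list(H)
  for (t in seq_len(L)) {
    ly <- params$layers[[t]]
    if (spec$layer_family == "graphconv") {
      KH <- as.matrix(bops$S1$K %*% H)
      Pre <- H %*% ly$W1 + KH %*% ly$W2 + rep(ly$b, each = nrow(H))
      is_last <- t == L
      act <- if (is_last) spec$output_activation else "lrelu"
      Hn <- apply_act(Pre, act, spec$slope)
      caches[[t]] <- list(H = H, KH = KH, Pre = Pre, out = Hn, act = act)
      H <- Hn
    } else {
      M1 <- as.matrix(bops$S1$K %*% H)
      M2 <- as.matrix(bops$S2$K %*% H)
      Hn <- cbind(M1 %*% ly$W1, M2 %*% ly$W2)
      caches[[t]] <- list(H = H, M1 = M1, M2 = M2)
      H <- Hn
      intermediates[[t + 1]] <- H
    }
  }
  if (spec$layer_family == "graphconv") {
    Y <- H # already activated
    out <- bn_unfold(Y, B, n)
    cc <- list(V = V, A0 = A0, H0m = H0m, caches = caches, B = B)
  } else {
    Hcat <- do.call(cbind, intermediates)
    Ylin <- Hcat %*% params$Wc
    Y <- apply_act(Ylin, spec$output_activation, spec$slope)
    out <- bn_unfold(Y, B, n)
    cc <- list(V = V, A0 = A0, H0m = H0m, caches = caches,
               intermediates = intermediates, Hcat = Hcat, Ylin = Ylin,
               Yact = Y, B = B)
  }
  if (cache) list(out = out, cache = cc) else list(out = out)
}

gen_backward <- function(params, spec, bops, cache, dOut, latent_dim) {
  B <- cache$B; n <- spec$n_genes
  L <- spec$n_mp_layers
  grads <- list(WI = NULL, bI = NULL, layers = vector("list", L))
  if (spec$layer_family == "graphconv") {
    dH <- bn_fold(dOut)
    for (t in L:1) {
      cc <- cache$caches[[t]]
      ly <- params$layers[[t]]
      dPre <- dH * act_grad_from(cc$Pre, cc$out, cc$act, spec$slope)
      grads$layers[[t]] <- list(W1 = crossprod(cc$H, dPre),
                                W2 = crossprod(cc$KH, dPre),
                                b = matrix(colSums(dPre), 1))
      dH <- tcrossprod(dPre, ly$W1) +
        as.matrix(bops$S1$Kt %*% tcrossprod(dPre, ly$W2))
    }
    dH0 <- dH
  } else {
    dY <- bn_fold(dOut) *
      act_grad_from(cache$Ylin, cache$Yact, spec$output_activation, spec$slope)
    grads$Wc <- crossprod(cache$Hcat, dY)
    dHcat <- dY %*% t(params$Wc)
    widths <- vapply(cache$intermediates, ncol, integer(1))
    offs <- cumsum(c(0, widths))
    dInter <- lapply(seq_along(widths), function(i)
      dHcat[, (offs[i] + 1):offs[i + 1], drop = FALSE])
    dH <- dInter[[L + 1]]
    for (t in L:1) {
      cc <- cache$caches[[t]]
      ly <- params$layers[[t]]
      w <- ncol(ly$W1)
      d1 <- dH[, seq_len(w), drop = FALSE]
      d2 <- dH[, w + seq_len(w), drop = FALSE]
      grads$layers[[t]] <- list(W1 = crossprod(cc$M1, d1),
                                W2 = crossprod(cc$M2, d2))
      dHprev <- as.matrix(bops$S1$Kt %*% (d1 %*% t(ly$W1))) +
        as.matrix(bops$S2$Kt %*% (d2 %*% t(ly$W2)))
      dH <- dHprev + dInter[[t]]
    }
    dH0 <- dH
  }
  dH0m <- bn_unfold(dH0, B, n)
  dA0 <- dH0m * lrelu_grad(cache$A0, spec$slope)
  grads$WI <- crossprod(cache$V, dA0)
  grads$bI <- matrix(colSums(dA0), 1)
  dV <- dA0 %*% t(params$WI)
  dZ <- dV[, seq_len(latent_dim), drop = FALSE]
  dCemb <- dV[, -seq_len(latent_dim), drop = FALSE]
  list(grads = grads, dZ = dZ, dCemb = dCemb)
}

#' Critic (Wasserstein discriminator) specification
#'
#' An MLP scoring each (expression, condition) pair with a single unbounded
#' scalar; default two hidden layers of 256 leaky-ReLU units, linear output
#' (no terminal squashing — the score approximates a Wasserstein potential).
#'
#' @param n_genes expression input width.
#' @param m conditioning width (0 disables conditioning).
#' @param hidden hidden layer widths.
#' @param slope leaky-ReLU slope.
#' @return a [new_mlp()] network tagged with the conditioning width.
#' @export
critic_network <- function(n_genes, m = 0, hidden = c(256, 256),
                           slope = 0.2) {
  net <- new_mlp(c(n_genes + m, hidden, 1), act = "lrelu",
                 out_act = "identity", slope = slope)
  net$n_genes <- n_genes
  net$m <- m
  net
}

#' Critic score
#' @param critic a [critic_network()].
#' @param X expression batch (rows = samples).
#' @param Cemb conditioning batch (or `NULL` when unconditioned).
#' @return numeric vector of unbounded scores.
#' @export
critic_score <- function(critic, X, Cemb = NULL) {
  inp <- if (is.null(Cemb) || !ncol(Cemb)) X else cbind(X, Cemb)
  if (ncol(inp) != critic$dims[1])
    se_stop("critic input width mismatch", class = "synexpr_validation_error")
  drop(mlp_forward(critic, inp)$out)
}

#' Assemble a baseline model bundle
#'
#' * `gan` — fully connected generator + discriminator (2 x 256 leaky-ReLU),
#'   trained with the original saturating cross-entropy objective;
#' * `wgan_gp` — same fully connected networks, Wasserstein loss with
#'   gradient penalty;
#' * `cvae` — conditional VAE: encoder and decoder with a single hidden layer
#'   of 256 units and a 64-dimensional Gaussian latent space, trained on the
#'   evidence lower bound (reconstruction + KL).
#'
#' @param kind `"gan"`, `"wgan_gp"` or `"cvae"`.
#' @param n_genes number of genes.
#' @param m conditioning width.
#' @param latent_dim latent dimension (64 by default; fixed at 64 for cvae).
#' @param hidden hidden widths for gan/wgan_gp networks.
#' @param output_activation generator/decoder output activation.
#' @return list bundle with the networks and a `kind` tag.
#' @export
build_baseline <- function(kind = c("gan", "wgan_gp", "cvae"), n_genes,
                           m = 0, latent_dim = 64, hidden = c(256, 256),
                           output_activation = "sigmoid") {
  kind <- match.arg(kind)
  if (kind == "cvae") {
    latent_dim <- 64
    enc <- new_mlp(c(n_genes + m, 256, 2 * latent_dim))
    dec <- new_mlp(c(latent_dim + m, 256, n_genes),
                   out_act = output_activation)
    return(list(kind = kind, encoder = enc, decoder = dec,
                latent_dim = latent_dim, n_genes = n_genes, m = m))
  }
  gen <- new_mlp(c(latent_dim + m, hidden, n_genes),
                 out_act = output_activation)
  crit <- critic_network(n_genes, m, hidden)
  list(kind = kind, generator = gen, critic = crit,
       latent_dim = latent_dim, n_genes = n_genes, m = m)
}
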