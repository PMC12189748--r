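# Embeddings, generator layer equations, critic, baselines.

path3 <- function() # undirected path a-b-c with unit weights
  gene_graph(c("a", "b", "c"),
             tibble::tibble(from = c(1, 2), to = c(2, 3), weight = 1),
             directed = FALSE)

test_that("embedding dimension rules", {
  expect_identical(embedding_dim(20, "paper_literal"), 21L)
  expect_identical(embedding_dim(1, "paper_literal"), 2L)
  expect_identical(embedding_dim(20, "sqrt_plus_one"), 5L)
  expect_error(embedding_dim(0), class = "synexpr_validation_error")
})

test_that("covariate embedding concatenates per-covariate blocks", {
  set.seed(2)
  emb <- covariate_embedding(list(u = c("a", "b"), v = c("x", "y", "z")),
                             rule = "sqrt_plus_one")
  # d = floor(sqrt(l)) + 1: 2 and 2
  expect_identical(emb$dims, c(u = 2L, v = 2L))
  expect_equal(emb$m, 4)
  codes <- rbind(c(1, 2), c(1, 2))
  E <- embed_covariates(emb, codes)
  expect_equal(dim(E), c(2, 4))
  expect_equal(E[1, ], E[2, ]) # deterministic lookup
  # changing one covariate changes only its slice
  E2 <- embed_covariates(emb, rbind(c(2, 2), c(1, 2)))
  expect_equal(E2[1, 3:4], E[1, 3:4])
  expect_false(isTRUE(all.equal(E2[1, 1:2], E[1, 1:2])))
  expect_error(embed_covariates(emb, rbind(c(3, 1))),
               class = "synexpr_validation_error")
})

test_that("initial node features follow h0 = sigma(W_I v + b_I)", {
  # zero weights: h0 equals the bias for every z (sigma(b) = b for b >= 0)
  spec <- generator_spec(3, "graphconv", latent_dim = 2, n_mp_layers = 1,
                         output_activation = "identity", slope = 1)
  emb <- covariate_embedding(list())
  params <- synexpr:::gen_init(spec, emb)
  params$WI <- matrix(0, 2, 3)
  params$bI <- matrix(c(0.3, 0.7, 0.1), 1)
  g0 <- gene_graph(c("a", "b", "c"), NULL, directed = FALSE)
  bops <- synexpr:::batch_ops(synexpr:::gen_operators(spec, g0), 2)
  params$layers[[1]]$W1 <- matrix(1); params$layers[[1]]$W2 <- matrix(1)
  Z <- matrix(rnorm(4), 2, 2)
  fw <- synexpr:::gen_forward(params, spec, bops, Z, matrix(0, 2, 0),
                              cache = TRUE)
  # empty graph + unit W1 + identity activations: output == h0 == bias row
  expect_equal(fw$out, matrix(rep(c(0.3, 0.7, 0.1), each = 2), 2, 3))

  # 2 genes, d = 1, m = 0, W_I = [[1], [-1]], sigma = identity, z = 3
  spec2 <- generator_spec(2, "graphconv", latent_dim = 1, n_mp_layers = 1,
                          output_activation = "identity", slope = 1)
  p2 <- synexpr:::gen_init(spec2, emb)
  p2$WI <- matrix(c(1, -1), 1, 2); p2$bI <- matrix(0, 1, 2)
  p2$layers[[1]]$W1 <- matrix(1); p2$layers[[1]]$W2 <- matrix(1)
  p2$layers[[1]]$b <- matrix(0, 1, 1)
  g2 <- gene_graph(c("a", "b"), NULL, directed = FALSE)
  b2 <- synexpr:::batch_ops(synexpr:::gen_operators(spec2, g2), 1)
  fw2 <- synexpr:::gen_forward(p2, spec2, b2, matrix(3, 1, 1),
                               matrix(0, 1, 0))
  expect_equal(fw2$out, matrix(c(3, -3), 1, 2))
  # determinism: same inputs, same outputs
  fw3 <- synexpr:::gen_forward(p2, spec2, b2, matrix(3, 1, 1),
                               matrix(0, 1, 0))
  expect_identical(fw2$out, fw3$out)
})

test_that("the 1-hop layer reproduces the hand-computed update (3, 2)", {
  # 2 nodes, single directed edge 2 -> 1 weight 1, h = (1, 2), W1 = W2 = 1
  spec <- generator_spec(2, "graphconv", latent_dim = 1, n_mp_layers = 1,
                         output_activation = "identity", slope = 1)
  emb <- covariate_embedding(list())
  params <- synexpr:::gen_init(spec, emb)
  params$WI <- matrix(c(1, 2), 1, 2) # h0 = (1, 2) for z = 1
  params$bI <- matrix(0, 1, 2)
  params$layers[[1]]$W1 <- matrix(1)
  params$layers[[1]]$W2 <- matrix(1)
  params$layers[[1]]$b <- matrix(0, 1, 1)
  g <- gene_graph(c("a", "b"),
                  tibble::tibble(from = 2, to = 1, weight = 1),
                  directed = TRUE, signed = TRUE)
  bops <- synexpr:::batch_ops(synexpr:::gen_operators(spec, g), 1)
  fw <- synexpr:::gen_forward(params, spec, bops, matrix(1, 1, 1),
                              matrix(0, 1, 0))
  # node a: h_a * W1 + A[b,a] * h_b * W2 = 1 + 2 = 3; node b: self only = 2
  expect_equal(fw$out, matrix(c(3, 2), 1, 2))
})

test_that("heterophily layer separates 1-hop and 2-hop aggregates", {
  # path a-b-c, h = (1, 0, 1): node a's block is (0 || 1) under
  # square-root degree normalization
  g <- path3()
  ops <- synexpr:::h2gcn_operators(g, normalization = "sym_sqrt_degree")
  h <- matrix(c(1, 0, 1), 3, 1)
  agg1 <- as.matrix(ops$S1 %*% h)
  agg2 <- as.matrix(ops$S2 %*% h)
  expect_equal(agg1[1, 1], 0)        # h_b / sqrt(deg(a) deg(b)) = 0
  expect_equal(agg2[1, 1], 1)        # h_c / sqrt(deg(a) deg(c)) = 1
  expect_equal(agg1[2, 1], 2 / sqrt(2)) # (h_a + h_c) / sqrt(2 * 1)
  expect_equal(agg2[2, 1], 0)        # b has no exact-distance-2 neighbour

  # graph with no length-2 paths: 2-hop block all zeros
  g1 <- gene_graph(c("a", "b"), tibble::tibble(from = 1, to = 2, weight = 1),
                   directed = FALSE)
  ops1 <- synexpr:::h2gcn_operators(g1)
  expect_equal(sum(abs(ops1$S2)), 0)

  # product_degree is the literal alternative
  opsP <- synexpr:::h2gcn_operators(g, normalization = "product_degree")
  expect_equal(as.matrix(opsP$S1)[2, 1], 2) # A * |N(b)||N(a)| = 1 * 2 * 1
})

test_that("h2gcn readout concatenates all intermediate representations", {
  set.seed(8)
  spec <- generator_spec(3, "h2gcn", latent_dim = 2, n_mp_layers = 3,
                         output_activation = "identity")
  emb <- covariate_embedding(list())
  params <- synexpr:::gen_init(spec, emb)
  # widths double per layer: 1, 2, 4, 8 -> concatenated width 15
  expect_equal(nrow(params$Wc), 15)
  bops <- synexpr:::batch_ops(synexpr:::gen_operators(spec, path3()), 4)
  fw <- synexpr:::gen_forward(params, spec, bops, matrix(rnorm(8), 4, 2),
                              matrix(0, 4, 0), cache = TRUE)
  expect_equal(dim(fw$out), c(4, 3))
  expect_equal(ncol(fw$cache$Hcat), 15)
  # readout is the plain projection of the concatenated representations
  expect_equal(fw$cache$Ylin, fw$cache$Hcat %*% params$Wc)
  # layer output width doubles the input width (square W1, W2)
  for (t in 1:3)
    expect_equal(ncol(fw$cache$caches[[t]]$H) * 2,
                 if (t < 3) ncol(fw$cache$caches[[t + 1]]$H) else
                   ncol(fw$cache$intermediates[[4]]))
})

test_that("graph ablation: empty graph reduces the generator to a dense stack", {
  set.seed(14)
  n <- 5
  spec <- generator_spec(n, "graphconv", latent_dim = 3, n_mp_layers = 3,
                         node_dim = 4, output_activation = "sigmoid")
  emb <- covariate_embedding(list())
  params <- synexpr:::gen_init(spec, emb)
  g0 <- gene_graph(paste0("g", 1:n), NULL, directed = FALSE)
  bops <- synexpr:::batch_ops(synexpr:::gen_operators(spec, g0), 2)
  Z <- matrix(rnorm(6), 2, 3)
  out <- synexpr:::gen_forward(params, spec, bops, Z, matrix(0, 2, 0))$out
  # hand-built dense-only forward on shared parameters (message terms vanish)
  h <- synexpr:::lrelu(sweep(Z %*% params$WI, 2, params$bI, "+"), spec$slope)
  hv <- matrix(as.vector(t(h)), ncol = 1)
  for (t in 1:3) {
    pre <- sweep(hv %*% params$layers[[t]]$W1, 2, params$layers[[t]]$b, "+")
    hv <- if (t < 3) synexpr:::lrelu(pre, spec$slope)
    else synexpr:::sigmoid(pre)
  }
  expect_equal(out, matrix(as.vector(hv), 2, n, byrow = TRUE))
})

test_that("message-passing locality: far nodes cannot influence a gene", {
  # directed chain 1 -> 2 -> 3 -> 4 -> 5, L = 2 layers, W1 (self path) = 0:
  # gene 5 aggregates from distance <= 2, so perturbing node 1's initial
  # embedding must not change gene 5's output
  n <- 5
  spec <- generator_spec(n, "graphconv", latent_dim = 1, n_mp_layers = 2,
                         node_dim = 3, output_activation = "identity")
  emb <- covariate_embedding(list())
  set.seed(31)
  params <- synexpr:::gen_init(spec, emb)
  for (t in 1:2) params$layers[[t]]$W1[] <- 0
  g <- gene_graph(paste0("g", 1:n),
                  tibble::tibble(from = 1:4, to = 2:5, weight = 1),
                  directed = TRUE, signed = TRUE)
  bops <- synexpr:::batch_ops(synexpr:::gen_operators(spec, g), 1)
  Z <- matrix(0.7, 1, 1)
  base <- synexpr:::gen_forward(params, spec, bops, Z, matrix(0, 1, 0))$out
  p2 <- params
  p2$bI[1, 1] <- p2$bI[1, 1] + 5 # perturb node 1's initial embedding only
  pert <- synexpr:::gen_forward(p2, spec, bops, Z, matrix(0, 1, 0))$out
  expect_equal(pert[1, 5], base[1, 5])   # distance 4 > L: unchanged
  expect_false(pert[1, 3] == base[1, 3]) # distance 2 <= L: changed
})

test_that("generator forward obeys codomain, shape and determinism", {
  set.seed(77)
  fxg <- gene_graph(paste0("g", 1:6),
                    tibble::tibble(from = c(1, 2, 3), to = c(2, 3, 4),
                                   weight = c(1, -1, 1)),
                    directed = TRUE, signed = TRUE)
  emb <- covariate_embedding(list(cond = c("A", "B")))
  for (fam in c("graphconv", "h2gcn")) {
    spec <- generator_spec(6, fam, latent_dim = 4, n_mp_layers = 2,
                           output_activation = "sigmoid")
    params <- synexpr:::gen_init(spec, emb)
    bops <- synexpr:::batch_ops(synexpr:::gen_operators(spec, fxg), 3)
    Z <- matrix(rnorm(12), 3, 4)
    Cemb <- embed_covariates(emb, matrix(c(1, 2, 1), 3, 1))
    o1 <- synexpr:::gen_forward(params, spec, bops, Z, Cemb)$out
    o2 <- synexpr:::gen_forward(params, spec, bops, Z, Cemb)$out
    expect_equal(dim(o1), c(3, 6))
    expect_true(all(o1 > 0 & o1 < 1))
    expect_identical(o1, o2)
  }
})

test_that("critic scores are scalar, finite and condition-sensitive", {
  set.seed(5)
  cr <- critic_network(4, m = 2)
  X <- matrix(rnorm(12), 3, 4)
  # zero-initialized final layer: score 0 for any input
  cr0 <- cr; cr0$W[[3]][] <- 0; cr0$b[[3]][] <- 0
  expect_equal(critic_score(cr0, X, matrix(0, 3, 2)), rep(0, 3))
  # finite for large-magnitude inputs (no squashing overflow)
  big <- critic_score(cr, matrix(1e3, 2, 4), matrix(1e3, 2, 2))
  expect_true(all(is.finite(big)))
  # conditioning changes the score when c changes, all else fixed
  s1 <- critic_score(cr, X, matrix(0, 3, 2))
  s2 <- critic_score(cr, X, matrix(1, 3, 2))
  expect_false(isTRUE(all.equal(s1, s2)))
  expect_error(critic_score(cr, X, NULL),
               class = "synexpr_validation_error")
})

test_that("baseline bundles have the published layouts", {
  set.seed(6)
  cv <- build_baseline("cvae", n_genes = 10, m = 3)
  expect_equal(cv$latent_dim, 64)
  expect_equal(cv$encoder$dims, c(13, 256, 128))
  expect_equal(cv$decoder$dims, c(67, 256, 10))
  wg <- build_baseline("wgan_gp", n_genes = 10, m = 0, latent_dim = 8)
  expect_equal(wg$generator$dims, c(8, 256, 256, 10))
  fake <- mlp_forward(wg$generator, matrix(rnorm(16), 2, 8))$out
  expect_equal(ncol(fake), 10)
  expect_error(build_baseline("flow", 10), "arg")
})

test_that("permuting gene order permutes the graphconv output identically", {
  set.seed(50)
  n <- 5
  spec <- generator_spec(n, "graphconv", latent_dim = 2, n_mp_layers = 2,
                         node_dim = 3, output_activation = "identity")
  emb <- covariate_embedding(list())
  params <- synexpr:::gen_init(spec, emb)
  e <- tibble::tibble(from = c(1, 2, 4), to = c(2, 3, 5), weight = c(1, -1, 1))
  g <- gene_graph(paste0("g", 1:n), e, directed = TRUE, signed = TRUE)
  perm <- c(3, 5, 1, 2, 4) # new index of each old node
  gp <- gene_graph(paste0("g", 1:n)[order(perm)],
                   tibble::tibble(from = perm[e$from], to = perm[e$to],
                                  weight = e$weight),
                   directed = TRUE, signed = TRUE)
  pp <- params
  pp$WI <- params$WI[, order(perm), drop = FALSE]
  pp$bI <- params$bI[, order(perm), drop = FALSE]
  Z <- matrix(rnorm(2), 1, 2)
  o <- synexpr:::gen_forward(params, spec,
                             synexpr:::batch_ops(synexpr:::gen_operators(spec, g), 1),
                             Z, matrix(0, 1, 0))$out
  op <- synexpr:::gen_forward(pp, spec,
                              synexpr:::batch_ops(synexpr:::gen_operators(spec, gp), 1),
                              Z, matrix(0, 1, 0))$out
  expect_equal(op[1, ], o[1, order(perm)])
})

test_that("the mean aggregator averages in-neighbor contributions", {
  spec_sum <- generator_spec(3, "graphconv", latent_dim = 1, n_mp_layers = 1,
                             output_activation = "identity", slope = 1,
                             aggregator = "sum")
  spec_mean <- generator_spec(3, "graphconv", latent_dim = 1, n_mp_layers = 1,
                              output_activation = "identity", slope = 1,
                              aggregator = "mean")
  emb <- covariate_embedding(list())
  params <- synexpr:::gen_init(spec_sum, emb)
  params$WI <- matrix(c(0, 1, 3), 1, 3) # h0 = (0, 1, 3) for z = 1
  params$bI <- matrix(0, 1, 3)
  params$layers[[1]] <- list(W1 = matrix(1), W2 = matrix(1),
                             b = matrix(0, 1, 1))
  g <- gene_graph(paste0("g", 1:3),
                  tibble::tibble(from = c(2, 3), to = c(1, 1), weight = 1),
                  directed = TRUE, signed = TRUE)
  Z <- matrix(1, 1, 1); C0 <- matrix(0, 1, 0)
  o_sum <- synexpr:::gen_forward(params, spec_sum,
    synexpr:::batch_ops(synexpr:::gen_operators(spec_sum, g), 1), Z, C0)$out
  o_mean <- synexpr:::gen_forward(params, spec_mean,
    synexpr:::batch_ops(synexpr:::gen_operators(spec_mean, g), 1), Z, C0)$out
  expect_equal(o_sum[1, 1], 0 + (1 + 3))   # weighted sum of both parents
  expect_equal(o_mean[1, 1], 0 + (1 + 3) / 2) # average over |N(1)| = 2
  expect_equal(o_sum[1, 2:3], o_mean[1, 2:3]) # isolated nodes unaffected
})
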