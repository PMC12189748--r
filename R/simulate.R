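# Seeded simulator: signed regulatory graphs plus linear-Gaussian
# structural-equation sampling of expression with class-conditional means,
# so every module can be exercised without external data.

#' Simulation specification
#'
#' Describes the synthetic world: a signed directed acyclic regulatory graph
#' among `n_genes` genes with `n_tf` regulators, and samples drawn from a
#' linear structural equation model (SEM) in topological order:
#' `x_j = mu_{class(sample), j} + sum_{i in parents(j)} w_ij * sign_ij * x_i
#' + eps_j`, `eps_j ~ N(0, noise_sd^2)`. Class-conditional means attach to
#' *root* genes (regulators and unregulated genes) and propagate to targets
#' through the edges — condition effects enter at the top of the regulatory
#' hierarchy, as they do for environmental covariates acting on transcription
#' factors.
#'
#' @param n_genes,n_tf gene and regulator counts (`n_tf <= n_genes`).
#' @param edge_prob probability of each admissible regulator->target edge.
#' @param repression_prob probability an edge is repressive (weight -1).
#' @param n_samples number of samples.
#' @param conditions named list of per-covariate class-proportion vectors
#'   (named proportions; may include an imbalanced `"MISSING"` class).
#' @param effect_size sd of the per-(class, gene) mean shifts.
#' @param edge_weight_range range of SEM edge-weight magnitudes.
#' @param noise_sd SEM noise standard deviation (> 0).
#' @param link optional nonlinearity hook: a function applied to the summed
#'   parent contribution of every regulated gene (`NULL` keeps the SEM
#'   linear, the default).
#' @param seed RNG seed.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 50, n_tf = 10, edge_prob = 0.02,
                     repression_prob = 0.3, n_samples = 500,
                     conditions = list(condition = c(A = 0.5, B = 0.5)),
                     effect_size = 1, edge_weight_range = c(0.5, 1),
                     noise_sd = 0.3, link = NULL, seed = 1) {
  stopifnot(n_tf <= n_genes, edge_prob >= 0, edge_prob <= 1,
            repression_prob >= 0, repression_prob <= 1, noise_sd > 0,
            length(edge_weight_range) == 2)
  for (pp in conditions)
    if (abs(sum(pp) - 1) > 1e-8)
      se_stop("condition class proportions must sum to 1")
  structure(list(n_genes = n_genes, n_tf = n_tf, edge_prob = edge_prob,
                 repression_prob = repression_prob, n_samples = n_samples,
                 conditions = conditions, effect_size = effect_size,
                 edge_weight_range = edge_weight_range, noise_sd = noise_sd,
                 link = link, seed = seed),
            class = "sim_spec")
}

#' Simulate a signed regulatory graph
#'
#' Regulators are genes 1..n_tf; each admissible pair (regulator i -> gene j
#' with j > i, guaranteeing acyclicity) receives an edge independently with
#' probability `edge_prob`. Edges are repressive (weight -1) with probability
#' `repression_prob`, otherwise activating (+1). SEM weight magnitudes drawn
#' from `edge_weight_range` are stored in `meta$magnitude`, aligned to the
#' edge list.
#'
#' @param spec a [sim_spec()].
#' @return directed signed [gene_graph()] (weights in {-1, +1}).
#' @export
simulate_grn <- function(spec) {
  set.seed(spec$seed)
  gene_ids <- sprintf("g%03d", seq_len(spec$n_genes))
  from <- integer(); to <- integer()
  for (i in seq_len(spec$n_tf)) {
    targets <- if (i < spec$n_genes) (i + 1):spec$n_genes else integer()
    hit <- targets[runif(length(targets)) < spec$edge_prob]
    from <- c(from, rep(i, length(hit))); to <- c(to, hit)
  }
  sgn <- ifelse(runif(length(from)) < spec$repression_prob, -1, 1)
  mag <- runif(length(from), spec$edge_weight_range[1],
               spec$edge_weight_range[2])
  gene_graph(gene_ids,
             tibble::tibble(from = from, to = to, weight = sgn),
             directed = TRUE, signed = TRUE,
             meta = list(kind = "simulated_grn", magnitude = mag,
                         n_tf = spec$n_tf, edge_prob = spec$edge_prob))
}

# regulon-structured planted graph: each regulator controls a disjoint block
# of targets. Single-parent targets keep parent-child correlations above the
# co-expression threshold (two comparable independent parents would cap the
# correlation at 1/sqrt(2)).
regulon_graph <- function(n_genes, n_tf, targets_per_tf, repression_prob,
                          weight_range, seed) {
  set.seed(seed)
  stopifnot(n_tf * targets_per_tf <= n_genes - n_tf)
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  from <- integer(); to <- integer()
  nxt <- n_tf + 1L
  for (i in seq_len(n_tf)) {
    tg <- nxt:(nxt + targets_per_tf - 1L)
    from <- c(from, rep(i, length(tg))); to <- c(to, tg)
    nxt <- nxt + targets_per_tf
  }
  sgn <- ifelse(runif(length(from)) < repression_prob, -1, 1)
  mag <- runif(length(from), weight_range[1], weight_range[2])
  gene_graph(gene_ids, tibble::tibble(from = from, to = to, weight = sgn),
             directed = TRUE, signed = TRUE,
             meta = list(kind = "regulon_grn", magnitude = mag, n_tf = n_tf))
}

# Kahn topological order; errors on cycles
topological_order <- function(graph) {
  n <- length(graph$gene_ids)
  e <- graph$edges
  indeg <- tabulate(e$to, n)
  children <- split(seq_len(nrow(e)), e$from)
  queue <- which(indeg == 0)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ei in children[[as.character(v)]]) {
      tgt <- e$to[ei]
      indeg[tgt] <- indeg[tgt] - 1L
      if (indeg[tgt] == 0) queue <- c(queue, tgt)
    }
  }
  if (length(order) < n)
    se_stop("graph contains a cycle; the SEM needs an acyclic graph",
            class = "synexpr_validation_error")
  order
}

#' Sample expression from a planted regulatory graph
#'
#' Linear-Gaussian SEM in topological order (see [sim_spec()]). Edge-weight
#' magnitudes come from `graph$meta$magnitude` when present (as written by
#' [simulate_grn()]), otherwise they are drawn from `spec$edge_weight_range`.
#' Covariate classes are sampled from the declared proportions; per-(class,
#' gene) root mean shifts are drawn once with sd `effect_size`. Deterministic
#' under `spec$seed`.
#'
#' @param graph an acyclic directed signed [gene_graph()].
#' @param spec a [sim_spec()].
#' @return list with `X` (raw-space [expression_matrix()]), `C` (a
#'   `cov_table`) and `weights` (tibble of realized signed SEM weights).
#' @export
simulate_expression <- function(graph, spec) {
  set.seed(spec$seed + 1L)
  n <- length(graph$gene_ids)
  ns <- spec$n_samples
  ord <- topological_order(graph)
  e <- graph$edges
  mag <- graph$meta$magnitude
  if (is.null(mag) || length(mag) != nrow(e))
    mag <- runif(nrow(e), spec$edge_weight_range[1],
                 spec$edge_weight_range[2])
  w <- e$weight * mag
  # covariates
  covs <- lapply(spec$conditions, function(pp) {
    sample(names(pp), ns, replace = TRUE, prob = pp)
  })
  Cdf <- tibble::as_tibble(covs)
  Cdf$sample_id <- sprintf("s%04d", seq_len(ns))
  C <- covariate_table(Cdf[, c("sample_id", names(spec$conditions))])
  # class-conditional root means: one shift per (covariate, class, gene)
  roots <- setdiff(seq_len(n), unique(e$to))
  mu <- matrix(0, ns, n)
  for (vn in names(spec$conditions)) {
    classes <- names(spec$conditions[[vn]])
    shifts <- matrix(rnorm(length(classes) * n, sd = spec$effect_size),
                     length(classes), n,
                     dimnames = list(classes, NULL))
    shifts[, setdiff(seq_len(n), roots)] <- 0
    mu <- mu + shifts[as.character(C[[vn]]), , drop = FALSE]
  }
  X <- mu + matrix(rnorm(ns * n, sd = spec$noise_sd), ns, n)
  parents <- split(seq_len(nrow(e)), e$to)
  link <- if (is.null(spec$link)) identity else spec$link
  for (j in ord) {
    pe <- parents[[as.character(j)]]
    if (length(pe))
      X[, j] <- X[, j] +
        link(drop(as.matrix(X[, e$from[pe], drop = FALSE]) %*% w[pe]))
  }
  colnames(X) <- graph$gene_ids
  rownames(X) <- Cdf$sample_id
  list(X = expression_matrix(X, space = "raw"), C = C,
       weights = tibble::tibble(from = graph$gene_ids[e$from],
                                to = graph$gene_ids[e$to],
                                sign = e$weight, weight = w))
}

#' Ready-made simulation fixtures
#'
#' Three deterministic bundles used throughout the test-suite and examples:
#' * `tiny` — 20 genes x 64 samples, 2 balanced classes, 4 regulons of 3;
#' * `small` — 50 genes x 500 samples, 3 classes with an imbalanced
#'   `MISSING` class (0.5/0.3/0.2), 10 regulons of 4, planted |w| in
#'   \[0.8, 1\] at noise_sd 0.15 (the low-noise regime where strong planted
#'   edges are recoverable by a 0.8 correlation threshold);
#' * `medium` — 200 genes x 1000 samples, 5 classes, 20 regulons of 6.
#'
#' @param profile `"tiny"`, `"small"` or `"medium"`.
#' @return list with raw `X`, min-max normalized `Xn`, covariates `C`,
#'   planted `graph`, SEM `weights`, the fitted `normalizer`, the `spec`, and
#'   deterministic stratified `train_idx` / `test_idx` (70/30).
#' @export
make_fixture <- function(profile = c("tiny", "small", "medium")) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    tiny = list(n_genes = 20, n_tf = 4, tpt = 3, n_samples = 64,
                conditions = list(condition = c(A = 0.5, B = 0.5)),
                seed = 101),
    small = list(n_genes = 50, n_tf = 10, tpt = 4, n_samples = 500,
                 conditions = list(condition = c(A = 0.5, B = 0.3,
                                                 MISSING = 0.2)),
                 seed = 202),
    medium = list(n_genes = 200, n_tf = 20, tpt = 6, n_samples = 1000,
                  conditions = list(condition = c(A = 0.3, B = 0.25,
                                                  C = 0.2, D = 0.15,
                                                  E = 0.1)),
                  seed = 303))
  spec <- sim_spec(n_genes = cfg$n_genes, n_tf = cfg$n_tf,
                   repression_prob = 0.3, n_samples = cfg$n_samples,
                   conditions = cfg$conditions, effect_size = 1,
                   edge_weight_range = c(0.8, 1), noise_sd = 0.15,
                   seed = cfg$seed)
  graph <- regulon_graph(cfg$n_genes, cfg$n_tf, cfg$tpt,
                         repression_prob = spec$repression_prob,
                         weight_range = spec$edge_weight_range,
                         seed = cfg$seed)
  sim <- simulate_expression(graph, spec)
  normalizer <- fit_normalizer(sim$X, "minmax01")
  Xn <- apply_normalizer(sim$X, normalizer)
  # deterministic stratified 70/30 split on the first covariate
  set.seed(cfg$seed + 2L)
  lab <- as.character(sim$C[[covariate_names(sim$C)[1]]])
  train_idx <- sort(unlist(lapply(split(seq_along(lab), lab), function(ix)
    sample(ix, floor(0.7 * length(ix))))))
  test_idx <- setdiff(seq_along(lab), train_idx)
  list(X = sim$X, Xn = Xn, C = sim$C, graph = graph, weights = sim$weights,
       normalizer = normalizer, spec = spec, profile = profile,
       train_idx = train_idx, test_idx = unname(test_idx))
}

#' Write a fixture bundle to disk
#'
#' Standard text formats: expression and covariates as TSV, graph as edge
#' list + JSON sidecar, and a JSON manifest of the spec and seeds.
#' @param bundle a [make_fixture()] bundle.
#' @param dir output directory (created if needed).
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(bundle$X, file.path(dir, "expression.tsv"))
  write_covariate_table(bundle$C, file.path(dir, "covariates.tsv"))
  write_gene_graph(bundle$graph, file.path(dir, "graph.tsv"))
  readr::write_tsv(bundle$weights, file.path(dir, "sem_weights.tsv"),
                   progress = FALSE)
  manifest <- c(unclass(bundle$spec),
                list(profile = bundle$profile,
                     train_idx = bundle$train_idx,
                     test_idx = bundle$test_idx))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
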