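# Independent brute-force oracles used to freeze expected values. These stay
# deliberately naive (double loops, explicit ECDFs) and share no code with
# the implementations they check.

oracle_precision_recall <- function(A, B, t) {
  radii <- function(M) {
    sapply(seq_len(nrow(M)), function(i) {
      d <- sqrt(colSums((t(M) - M[i, ])^2))
      sort(d)[t + 1]
    })
  }
  rA <- radii(A); rB <- radii(B)
  in_manifold <- function(x, M, r) {
    any(sqrt(colSums((t(M) - x)^2)) <= r)
  }
  prec <- mean(sapply(seq_len(nrow(B)), function(i)
    in_manifold(B[i, ], A, rA)))
  rec <- mean(sapply(seq_len(nrow(A)), function(i)
    in_manifold(A[i, ], B, rB)))
  list(precision = prec, recall = rec)
}

oracle_correlation_coefficient <- function(A, B) {
  ca <- cor(A); cb <- cor(B)
  n <- ncol(A)
  a <- c(); b <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- c(a, ca[i, j]); b <- c(b, cb[i, j])
  }
  la <- mean(a); lb <- mean(b)
  ra <- sqrt(mean((a - la)^2)); rb <- sqrt(mean((b - lb)^2))
  mean((a - la) / ra * (b - lb) / rb)
}

oracle_ks_statistic <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- sapply(grid, function(g) mean(x <= g))
  fy <- sapply(grid, function(g) mean(y <= g))
  max(abs(fx - fy))
}

# Riemann-sum quantile-function oracle for the 1-D p-Wasserstein distance
oracle_wasserstein_1d <- function(x, y, p = 2, grid_n = 200000) {
  u <- (seq_len(grid_n) - 0.5) / grid_n
  qx <- sort(x)[ceiling(u * length(x))]
  qy <- sort(y)[ceiling(u * length(y))]
  (mean(abs(qx - qy)^p))^(1 / p)
}

oracle_edge_homophily <- function(graph, values, similarity) {
  e <- graph$edges
  s <- c()
  for (i in seq_len(nrow(e)))
    s <- c(s, similarity(values[e$from[i]], values[e$to[i]]))
  mean(s)
}

oracle_two_hop <- function(graph, node) {
  # BFS over the in-neighbor orientation used by message passing
  n <- length(graph$gene_ids)
  e <- edge_view(graph)
  inn <- function(v) unique(e$from[e$to == v])
  one <- inn(node)
  two <- unique(unlist(lapply(one, inn)))
  sort(setdiff(two, c(node, one)))
}

# shared fixtures kept cheap: memoize the heavier simulation bundles
fixture_env <- new.env(parent = emptyenv())
get_fixture <- function(profile) {
  if (is.null(fixture_env[[profile]]))
    fixture_env[[profile]] <- make_fixture(profile)
  fixture_env[[profile]]
}
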