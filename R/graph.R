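#' Sparse gene-gene graph
#'
#' Edges are stored as a sparse edge list of integer node indices into
#' `gene_ids`. Undirected graphs store each edge once with `from < to` and are
#' mirrored on demand; directed graphs store edges as (source -> target).
#' Signed graphs (regulatory networks) carry weights in {-1, +1}: +1 for
#' activation, -1 for repression. Dense adjacency is never materialized.
#'
#' @param gene_ids ordered character vector of node identifiers.
#' @param edges tibble/data.frame with integer columns `from`, `to` and a
#'   numeric `weight`.
#' @param directed logical.
#' @param signed logical; if `TRUE` weights must be -1 or +1.
#' @param meta named list of construction provenance.
#' @return object of class `gene_graph`.
#' @export
gene_graph <- function(gene_ids, edges, directed, signed = FALSE,
                       meta = list()) {
  gene_ids <- as.character(gene_ids)
  edges <- tibble::as_tibble(edges)
  if (!nrow(edges)) edges <- tibble::tibble(from = integer(), to = integer(),
                                            weight = double())
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  edges$weight <- as.double(edges$weight)
  n <- length(gene_ids)
  if (nrow(edges)) {
    if (any(edges$from < 1L | edges$from > n | edges$to < 1L | edges$to > n))
      se_stop("edge indices out of range", class = "synexpr_validation_error")
    if (any(edges$from == edges$to))
      se_stop("self-loops are not allowed", class = "synexpr_validation_error")
    if (signed && !all(edges$weight %in% c(-1, 1)))
      se_stop("signed graphs require weights in {-1, +1}",
              class = "synexpr_validation_error")
    if (!directed) {
      # canonical storage: from < to, one row per undirected edge
      flip <- edges$from > edges$to
      tmp <- edges$from[flip]; edges$from[flip] <- edges$to[flip]
      edges$to[flip] <- tmp
      edges <- dplyr::distinct(edges, .data$from, .data$to, .keep_all = TRUE)
    }
  }
  structure(list(gene_ids = gene_ids, edges = edges, directed = directed,
                 signed = signed, meta = meta),
            class = "gene_graph")
}

#' @method print gene_graph
#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("<gene_graph> %d genes, %d %s%s edges\n", length(x$gene_ids),
              nrow(x$edges), if (x$directed) "directed" else "undirected",
              if (x$signed) " signed" else ""))
  invisible(x)
}

#' Number of stored edges
#' @param graph a [gene_graph()].
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Symmetric edge view of a graph
#'
#' For undirected graphs returns both orientations of every stored edge; for
#' directed graphs returns the edge list as stored.
#' @param graph a [gene_graph()].
#' @export
edge_view <- function(graph) {
  e <- graph$edges
  if (graph$directed || !nrow(e)) return(e)
  dplyr::bind_rows(e, tibble::tibble(from = e$to, to = e$from,
                                     weight = e$weight))
}

#' Build a co-expression graph by thresholded correlation
#'
#' An undirected edge links genes i and j when the absolute Pearson
#' correlation of their expression profiles reaches `threshold`. The edge
#' weight is the (signed) correlation, or sign(corr) when `binarize = TRUE`.
#' Correlation is computed on the matrix exactly as given (normalize first if
#' the generator is trained in a normalized space). Constant genes produce no
#' edges. Column blocks keep memory linear in the number of retained edges.
#'
#' @param X an [expression_matrix()] or matrix (samples x genes).
#' @param threshold correlation threshold in (0, 1].
#' @param binarize replace weights by their sign.
#' @return undirected [gene_graph()].
#' @export
build_coexpression_graph <- function(X, threshold = 0.8, binarize = FALSE) {
  v <- as_expr_values(X)
  if (nrow(v) < 3) se_stop("need at least 3 samples to estimate correlations")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    se_stop("`threshold` must lie in (0, 1]", class = "synexpr_validation_error")
  p <- ncol(v)
  block <- 512L
  starts <- seq(1L, p, by = block)
  rows <- list()
  for (s in starts) {
    cols <- s:min(s + block - 1L, p)
    cc <- suppressWarnings(cor(v[, cols, drop = FALSE], v))
    cc[is.na(cc)] <- 0
    hit <- which(abs(cc) >= threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      from <- cols[hit[, 1]]
      to <- hit[, 2]
      keep <- from < to
      if (any(keep))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          from = from[keep], to = to[keep], weight = cc[hit][keep])
    }
  }
  edges <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(from = integer(), to = integer(), weight = double())
  if (binarize && nrow(edges)) edges$weight <- sign(edges$weight)
  gene_graph(colnames(v), edges, directed = FALSE, signed = FALSE,
             meta = list(kind = "coexpression", threshold = threshold,
                         corr = "pearson", binarize = binarize))
}

#' Tissue-specific co-expression graphs
#'
#' Builds one thresholded correlation graph per tissue (samples grouped by
#' `tissue_labels`); groups with fewer than 3 samples are skipped with a
#' warning. `combine = "union_max_abs"` merges all per-tissue graphs into a
#' single graph keeping, per gene pair, the weight of maximum absolute value —
#' the default used to condition a single generator. `combine = "per_tissue"`
#' returns the named list of graphs.
#'
#' @inheritParams build_coexpression_graph
#' @param tissue_labels per-sample categories (factor or character).
#' @param combine `"union_max_abs"` or `"per_tissue"`.
#' @export
build_tissue_graphs <- function(X, tissue_labels, threshold = 0.8,
                                combine = c("union_max_abs", "per_tissue"),
                                binarize = FALSE) {
  combine <- match.arg(combine)
  v <- as_expr_values(X)
  tissue_labels <- as.character(tissue_labels)
  if (length(tissue_labels) != nrow(v))
    se_stop("`tissue_labels` must have one entry per sample")
  graphs <- list()
  for (tt in unique(tissue_labels)) {
    idx <- which(tissue_labels == tt)
    if (length(idx) < 3) {
      warn(sprintf("tissue '%s' has %d samples (< 3); skipped", tt, length(idx)))
      next
    }
    g <- build_coexpression_graph(v[idx, , drop = FALSE], threshold, binarize)
    g$meta$tissue <- tt
    graphs[[tt]] <- g
  }
  if (!length(graphs)) se_stop("no tissue group with >= 3 samples")
  if (combine == "per_tissue") return(graphs)
  all_edges <- dplyr::bind_rows(lapply(graphs, function(g) g$edges))
  merged <- all_edges %>%
    dplyr::group_by(.data$from, .data$to) %>%
    dplyr::slice_max(abs(.data$weight), n = 1, with_ties = FALSE) %>%
    dplyr::ungroup()
  gene_graph(colnames(v), merged, directed = FALSE, signed = FALSE,
             meta = list(kind = "coexpression_union", threshold = threshold,
                         tissues = names(graphs), binarize = binarize))
}

#' Load a signed regulatory graph from an edge list
#'
#' TSV rows of (regulator, target, sign). Accepted sign tokens: `+`, `-`,
#' `+1`, `-1`, `1`, `activation`, `repression` (and `activator`/`repressor`/
#' `inhibition`). Activation is weighted +1, repression -1; regulation is
#' directed (not mirrored). Edges touching genes outside `gene_universe` are
#' dropped and counted in `meta$n_dropped`; self-loops are dropped and counted
#' in `meta$n_self`. Contradictory duplicates (same ordered pair with both
#' signs) keep the last occurrence with a warning.
#'
#' @param path edge-list TSV (optionally with a header line
#'   `source\ttarget\tsign`).
#' @param gene_universe ordered gene identifiers defining the node set.
#' @return directed signed [gene_graph()].
#' @export
load_regulatory_graph <- function(path, gene_universe) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^(source|regulator|from)\\b", lines[1],
                             ignore.case = TRUE))
    lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  gene_universe <- as.character(gene_universe)
  n_dropped <- 0L; n_self <- 0L
  from <- integer(); to <- integer(); w <- double()
  sign_map <- c("+" = 1, "-" = -1, "+1" = 1, "-1" = -1, "1" = 1,
                "activation" = 1, "activator" = 1,
                "repression" = -1, "repressor" = -1, "inhibition" = -1)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3)
      se_stop(sprintf("line %d: expected 3 tab-separated fields", i),
              class = "synexpr_parse_error")
    s <- sign_map[tolower(trimws(p[3]))]
    if (is.na(s))
      se_stop(sprintf("line %d: unparseable sign token '%s'", i, p[3]),
              class = "synexpr_parse_error")
    fi <- match(trimws(p[1]), gene_universe)
    ti <- match(trimws(p[2]), gene_universe)
    if (is.na(fi) || is.na(ti)) { n_dropped <- n_dropped + 1L; next }
    if (fi == ti) { n_self <- n_self + 1L; next }
    from <- c(from, fi); to <- c(to, ti); w <- c(w, unname(s))
  }
  if (length(from)) {
    key <- paste(from, to)
    dup <- duplicated(key, fromLast = TRUE)
    if (any(dup)) {
      contradictory <- vapply(unique(key[dup]), function(k) {
        length(unique(w[key == k])) > 1
      }, logical(1))
      if (any(contradictory))
        warn(sprintf("%d gene pair(s) listed with both signs; keeping the last occurrence",
                     sum(contradictory)))
      keep <- !dup
      from <- from[keep]; to <- to[keep]; w <- w[keep]
    }
  }
  gene_graph(gene_universe,
             tibble::tibble(from = from, to = to, weight = w),
             directed = TRUE, signed = TRUE,
             meta = list(kind = "regulatory", source = path,
                         n_dropped = n_dropped, n_self = n_self))
}

#' Serialize / read a gene graph
#'
#' Writes the edge list as TSV (`source`, `target`, `weight`) using gene
#' identifiers, plus a JSON sidecar `<path>.meta.json` holding the gene order
#' and construction metadata. `read_gene_graph()` restores the graph exactly.
#' @param graph a [gene_graph()].
#' @param path output TSV path.
#' @export
write_gene_graph <- function(graph, path) {
  e <- graph$edges
  out <- tibble::tibble(source = graph$gene_ids[e$from],
                        target = graph$gene_ids[e$to],
                        weight = e$weight)
  readr::write_tsv(out, path, progress = FALSE)
  side <- list(gene_ids = graph$gene_ids, directed = graph$directed,
               signed = graph$signed, meta = graph$meta)
  jsonlite::write_json(side, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_gene_graph
#' @export
read_gene_graph <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  e <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  gene_graph(side$gene_ids,
             tibble::tibble(from = match(e$source, side$gene_ids),
                            to = match(e$target, side$gene_ids),
                            weight = e$weight),
             directed = isTRUE(side$directed), signed = isTRUE(side$signed),
             meta = as.list(side$meta))
}

#' Edge homophily ratio
#'
#' Mean similarity over all stored edges:
#' `H(G) = (1/|E|) * sum over edges (i,j) of similarity(value_i, value_j)`.
#' Low values (heterophily) indicate connected genes carry dissimilar values,
#' the regime the 1-hop/2-hop separated aggregation is designed for.
#'
#' @param graph a [gene_graph()] with at least one edge.
#' @param node_values per-gene scalars or categories, aligned to `gene_ids`.
#' @param similarity function of two vectors returning values in \[0, 1\];
#'   defaults to the indicator of equality.
#' @return scalar in \[0, 1\].
#' @export
edge_homophily <- function(graph, node_values,
                           similarity = function(a, b) as.numeric(a == b)) {
  e <- graph$edges
  if (!nrow(e))
    se_stop("edge homophily is undefined for an empty edge set",
            class = "synexpr_undefined_error")
  if (length(node_values) != length(graph$gene_ids))
    se_stop("`node_values` must have one entry per gene")
  s <- similarity(node_values[e$from], node_values[e$to])
  if (any(s < 0 | s > 1)) se_stop("`similarity` must return values in [0, 1]")
  mean(s)
}

# neighborhood index sets under the message-passing orientation:
# undirected -> neighbors; directed -> in-neighbors (regulators of a gene)
neighbor_sets <- function(graph) {
  n <- length(graph$gene_ids)
  e <- edge_view(graph)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- integer()
  if (nrow(e)) {
    sp <- split(e$from, e$to)
    for (k in names(sp)) out[[as.integer(k)]] <- sort(unique(sp[[k]]))
  }
  out
}

#' Exact-distance-2 neighborhood
#'
#' Nodes at shortest-path distance exactly 2 from `node` (excluding the node
#' itself and its 1-hop neighbors). For directed graphs the neighborhood
#' orientation is in-neighbors: the regulators of a gene's regulators.
#'
#' @param graph a [gene_graph()].
#' @param node integer node index.
#' @return sorted integer vector of node indices.
#' @export
two_hop_neighbors <- function(graph, node) {
  n <- length(graph$gene_ids)
  if (node < 1 || node > n) se_stop("invalid node index")
  ns <- neighbor_sets(graph)
  one <- ns[[node]]
  two <- unique(unlist(ns[one], use.names = FALSE))
  sort(setdiff(two, c(node, one)))
}

#' Graph density as a percentage
#'
#' Directed: `100 * |E| / (n * (n - 1))`; undirected:
#' `100 * |E| / (n * (n - 1) / 2)` with each undirected edge counted once.
#' @param graph a [gene_graph()] with at least 2 genes.
#' @return percentage in \[0, 100\].
#' @export
graph_density <- function(graph) {
  n <- length(graph$gene_ids)
  if (n < 2) se_stop("graph density needs at least 2 genes")
  total <- if (graph$directed) n * (n - 1) else n * (n - 1) / 2
  100 * nrow(graph$edges) / total
}

# sparse message-passing operator S with S[i, j] = weight of edge j -> i
# (in-neighbor aggregation); undirected graphs contribute both orientations.
# abs_weights drops the sign of co-expression weights.
graph_operator <- function(graph, abs_weights = FALSE) {
  n <- length(graph$gene_ids)
  e <- edge_view(graph)
  w <- if (abs_weights) abs(e$weight) else e$weight
  Matrix::sparseMatrix(i = e$to, j = e$from, x = w, dims = c(n, n))
}

# degree-normalized 1-hop and 2-hop operators for the heterophily-aware layer.
# Degrees are neighborhood sizes |N(i)| under the same orientation; 2-hop
# neighbors enter with unit weight. normalization: "sym_sqrt_degree" divides
# by sqrt(|N(i)||N(j)|) (default), "product_degree" multiplies by the literal
# |N(i)||N(j)| product.
h2gcn_operators <- function(graph, abs_weights = FALSE,
                            normalization = c("sym_sqrt_degree",
                                              "product_degree")) {
  normalization <- match.arg(normalization)
  n <- length(graph$gene_ids)
  ns <- neighbor_sets(graph)
  # degree = neighborhood size under the message-passing orientation; nodes
  # with an empty neighborhood (e.g. unregulated TFs in a directed GRN) can
  # still be edge *sources*, so clamp at 1 to keep the scaling finite
  deg <- pmax(lengths(ns), 1L)
  e <- edge_view(graph)
  w1 <- if (abs_weights) abs(e$weight) else e$weight
  scale_fun <- function(i, j) {
    if (normalization == "sym_sqrt_degree") 1 / sqrt(deg[i] * deg[j])
    else deg[i] * deg[j]
  }
  S1 <- if (nrow(e))
    Matrix::sparseMatrix(i = e$to, j = e$from, x = w1 * scale_fun(e$to, e$from),
                         dims = c(n, n))
  else Matrix::sparseMatrix(i = integer(), j = integer(), x = double(),
                            dims = c(n, n))
  # exact-distance-2 pairs
  i2 <- integer(); j2 <- integer()
  for (v in seq_len(n)) {
    nb2 <- two_hop_neighbors(graph, v)
    if (length(nb2)) { i2 <- c(i2, rep(v, length(nb2))); j2 <- c(j2, nb2) }
  }
  S2 <- if (length(i2))
    Matrix::sparseMatrix(i = i2, j = j2, x = scale_fun(i2, j2), dims = c(n, n))
  else Matrix::sparseMatrix(i = integer(), j = integer(), x = double(),
                            dims = c(n, n))
  list(S1 = S1, S2 = S2, degree = deg)
}
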