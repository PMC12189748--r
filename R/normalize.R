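#' Fit a per-gene normalizer
#'
#' Two normalization schemes are supported, matching the preprocessing applied
#' to microarray and RNA-seq compendia respectively:
#' * `minmax01` — per-gene affine rescaling to \[0, 1\];
#' * `log2_zscore` — `log2(x + pseudocount)` followed by per-gene standard
#'   scaling. Standard scaling uses the *population* standard deviation
#'   (divide by n); the convention is fixed so that round trips are exact.
#'
#' Parameters are fitted only on the matrix passed here; applying the fitted
#' spec to held-out data may produce values outside the training range (no
#' clipping by default).
#'
#' @param X an [expression_matrix()] in raw space.
#' @param method `"minmax01"` or `"log2_zscore"`.
#' @param pseudocount nonnegative value added before log2.
#' @return an object of class `expr_normalizer`.
#' @export
fit_normalizer <- function(X, method = c("minmax01", "log2_zscore"),
                           pseudocount = 1) {
  method <- match.arg(method)
  v <- as_expr_values(X)
  if (inherits(X, "expr_mat") && X$space != "raw")
    se_stop("normalizers are fitted on raw-space data")
  if (method == "minmax01") {
    mn <- apply(v, 2, min)
    mx <- apply(v, 2, max)
    params <- tibble::tibble(gene_id = colnames(v), p1 = mn, p2 = mx,
                             degenerate = (mx - mn) == 0)
  } else {
    if (any(v + pseudocount <= 0))
      se_stop(sprintf(
        "log2 undefined: min(value + pseudocount) = %g <= 0; raise `pseudocount`",
        min(v) + pseudocount), class = "synexpr_domain_error")
    lg <- log2(v + pseudocount)
    mu <- colMeans(lg)
    # population sd: divide by n, documented convention
    sdv <- sqrt(colMeans(sweep(lg, 2, mu)^2))
    params <- tibble::tibble(gene_id = colnames(v), p1 = mu, p2 = sdv,
                             degenerate = sdv == 0)
  }
  structure(list(method = method, params = params, pseudocount = pseudocount),
            class = "expr_normalizer")
}

#' @method print expr_normalizer
#' @export
print.expr_normalizer <- function(x, ...) {
  cat(sprintf("<expr_normalizer> method = %s, %d genes (%d degenerate)\n",
              x$method, nrow(x$params), sum(x$params$degenerate)))
  invisible(x)
}

norm_params_for <- function(spec, gene_ids) {
  idx <- match(gene_ids, spec$params$gene_id)
  if (anyNA(idx))
    se_stop(paste0("genes not covered by the normalizer: ",
                   paste(gene_ids[is.na(idx)], collapse = ", ")),
            class = "synexpr_validation_error")
  spec$params[idx, ]
}

#' Apply or invert a fitted normalizer
#'
#' `apply_normalizer()` maps raw values into the normalized space;
#' `invert_normalizer()` maps them back. Degenerate (constant) genes map to 0
#' under both schemes and invert to their constant value. Out-of-range values
#' on held-out data are preserved unless `clip = TRUE` (useful when
#' post-processing generated samples).
#'
#' @param X an [expression_matrix()] (or bare matrix with gene columns).
#' @param spec an `expr_normalizer` from [fit_normalizer()].
#' @param clip clip `minmax01` output into \[0, 1\].
#' @return an [expression_matrix()] with the space tag updated.
#' @export
apply_normalizer <- function(X, spec, clip = FALSE) {
  v <- as_expr_values(X)
  pp <- norm_params_for(spec, colnames(v))
  if (spec$method == "minmax01") {
    rng <- pp$p2 - pp$p1
    rng[pp$degenerate] <- 1 # arbitrary; numerator forced to 0 below
    out <- sweep(sweep(v, 2, pp$p1), 2, rng, "/")
    out[, pp$degenerate] <- 0
    if (clip) out <- pmin(pmax(out, 0), 1)
    space <- "minmax01"
    if (!clip && any(out < -1e-9 | out > 1 + 1e-9)) {
      # held-out data can fall outside the training range; values are kept
      # (clipping is a presentation choice), bypassing the range invariant
      obj <- expression_matrix(pmin(pmax(out, 0), 1), space = "minmax01")
      obj$values <- out
      dimnames(obj$values) <- list(obj$sample_ids, obj$gene_ids)
      return(obj)
    }
    out <- pmin(pmax(out, 0), 1) # remove float fuzz within tolerance
  } else {
    if (any(v + spec$pseudocount <= 0))
      se_stop("log2 undefined for these values with the fitted pseudocount",
              class = "synexpr_domain_error")
    lg <- log2(v + spec$pseudocount)
    sdv <- pp$p2
    sdv[pp$degenerate] <- 1
    out <- sweep(sweep(lg, 2, pp$p1), 2, sdv, "/")
    out[, pp$degenerate] <- 0
    space <- "log2_zscore"
  }
  expression_matrix(out, space = space)
}

#' @rdname apply_normalizer
#' @export
invert_normalizer <- function(X, spec) {
  v <- as_expr_values(X)
  pp <- norm_params_for(spec, colnames(v))
  if (spec$method == "minmax01") {
    out <- sweep(sweep(v, 2, pp$p2 - pp$p1, "*"), 2, pp$p1, "+")
    out[, pp$degenerate] <- matrix(rep(pp$p1[pp$degenerate], each = nrow(v)),
                                   nrow = nrow(v))
  } else {
    sdv <- pp$p2
    out <- 2^(sweep(sweep(v, 2, sdv, "*"), 2, pp$p1, "+")) - spec$pseudocount
    if (any(pp$degenerate))
      out[, pp$degenerate] <- matrix(
        rep(2^pp$p1[pp$degenerate] - spec$pseudocount, each = nrow(v)),
        nrow = nrow(v))
  }
  expression_matrix(out, space = "raw")
}

#' Remove samples dominated by a few genes
#'
#' A sample is "greedy" when its `top_k` highest-expressed genes account for
#' more than `max_fraction` of its total expression. Such samples (seen in
#' bulk RNA-seq compendia, e.g. tissues dominated by a handful of transcripts)
#' distort per-gene scaling and are removed before training.
#'
#' @param X an [expression_matrix()] in raw space with nonnegative values.
#' @param top_k number of top genes considered (default 10).
#' @param max_fraction maximal allowed fraction of total expression carried by
#'   the top `top_k` genes (default 0.5).
#' @return list with `X` (filtered matrix) and `report`, a tibble of
#'   `sample_id`, `fraction`, `removed`.
#' @export
filter_greedy_samples <- function(X, top_k = 10, max_fraction = 0.5) {
  v <- as_expr_values(X)
  if (any(v < 0)) se_stop("greedy-sample filtering expects nonnegative values")
  k <- min(top_k, ncol(v))
  frac <- apply(v, 1, function(r) {
    tot <- sum(r)
    if (tot == 0) return(1) # empty sample: trivially dominated
    sum(sort(r, decreasing = TRUE)[seq_len(k)]) / tot
  })
  frac <- unname(frac)
  removed <- frac > max_fraction
  report <- tibble::tibble(sample_id = rownames(v), fraction = frac,
                           removed = removed)
  if (all(removed))
    se_stop("all samples removed; raise `max_fraction` or `top_k`")
  keep <- expression_matrix(v[!removed, , drop = FALSE],
                            space = if (inherits(X, "expr_mat")) X$space else "raw")
  list(X = keep, report = report)
}
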