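# Evaluation suite comparing a real and a synthetic expression matrix:
# manifold precision/recall, gene-gene correlation preservation,
# detectability, TSTR utility, per-gene KS tests and 1-D Wasserstein.

#' Manifold precision and recall
#'
#' Each dataset's support is estimated as a union of spheres, one per point,
#' with radius equal to the Euclidean distance to the point's t-th nearest
#' neighbour within the same set. Precision is the fraction of synthetic
#' points falling inside the real manifold; recall the fraction of real
#' points inside the synthetic manifold. Mode collapse shows up as high
#' precision with near-zero recall.
#'
#' @param X_real,X_syn matrices or [expression_matrix()]s with identical gene
#'   columns; each needs at least `t + 1` points.
#' @param t neighbour order (default 10).
#' @return list with `precision` and `recall`, both in \[0, 1\].
#' @export
precision_recall <- function(X_real, X_syn, t = 10) {
  A <- as_expr_values(X_real); B <- as_expr_values(X_syn)
  if (ncol(A) != ncol(B)) se_stop("feature dimensions differ")
  if (nrow(A) < t + 1 || nrow(B) < t + 1)
    se_stop(sprintf("need at least t + 1 = %d points in each set", t + 1),
            class = "synexpr_validation_error")
  radius <- function(M) {
    D <- cross_dist(M, M)
    apply(D, 1, function(dr) sort(dr)[t + 1]) # self-distance 0 is rank 1
  }
  rA <- radius(A); rB <- radius(B)
  inside <- function(points, ref, radii) {
    D <- cross_dist(points, ref)
    hit <- sweep(D, 2, radii, "<=")
    rowSums(hit) > 0
  }
  list(precision = mean(inside(B, A, rA)),
       recall = mean(inside(A, B, rB)))
}

#' Gene-gene correlation preservation coefficient
#'
#' Computes the full Pearson gene-gene correlation matrix in each dataset and
#' returns the Pearson correlation between the two sets of upper-triangle
#' entries (population-sd convention). 1 means the synthetic data reproduces
#' the pairwise co-expression structure exactly; 0 means none of it.
#'
#' @param X_real,X_syn matrices or [expression_matrix()]s with aligned genes,
#'   >= 2 genes and >= 3 samples each.
#' @return scalar in \[-1, 1\].
#' @export
correlation_coefficient <- function(X_real, X_syn) {
  A <- as_expr_values(X_real); B <- as_expr_values(X_syn)
  if (ncol(A) < 2 || nrow(A) < 3 || nrow(B) < 3)
    se_stop("need >= 2 genes and >= 3 samples per matrix")
  constA <- apply(A, 2, function(x) sd(x) == 0)
  constB <- apply(B, 2, function(x) sd(x) == 0)
  drop_genes <- constA | constB
  if (all(drop_genes) || sum(!drop_genes) < 2)
    se_stop("all gene pairs degenerate (constant genes)",
            class = "synexpr_undefined_error")
  if (any(drop_genes))
    warn(sprintf("%d constant gene(s) dropped pairwise", sum(drop_genes)))
  A <- A[, !drop_genes, drop = FALSE]; B <- B[, !drop_genes, drop = FALSE]
  ca <- cor(A); cb <- cor(B)
  ut <- upper.tri(ca)
  a <- ca[ut]; b <- cb[ut]
  # population-sd standardization of the pairwise values
  za <- (a - mean(a)) / sqrt(mean((a - mean(a))^2))
  zb <- (b - mean(b)) / sqrt(mean((b - mean(b))^2))
  mean(za * zb)
}

#' Detectability of synthetic data
#'
#' Trains binary classifiers to separate real (label 1) from synthetic
#' (label 0) samples: stratified 70/30 split, F1 (real as positive class) on
#' the held-out split, averaged over `n_runs` seeded repetitions. Lower is
#' better (chance level ~ 0.5 means indistinguishable). `space = "pc"`
#' projects both sets onto principal components fitted on the real training
#' split only (`k = min(n_pc, samples - 1, genes)`).
#'
#' @param X_real,X_syn matrices or [expression_matrix()]s, aligned genes.
#' @param classifiers subset of `c("lr", "mlp", "knn")`.
#' @param space `"full"` or `"pc"`.
#' @param n_pc number of principal components for `space = "pc"`.
#' @param n_runs number of seeded repetitions.
#' @param train_frac training fraction of the stratified split.
#' @param seed base seed.
#' @return tibble with one row per classifier x run and the F1 score.
#' @export
detectability <- function(X_real, X_syn, classifiers = c("lr", "mlp", "knn"),
                          space = c("full", "pc"), n_pc = 100, n_runs = 10,
                          train_frac = 0.7, seed = 1) {
  space <- match.arg(space)
  A <- as_expr_values(X_real); B <- as_expr_values(X_syn)
  if (!nrow(A) || !nrow(B)) se_stop("both sets must be nonempty")
  out <- list()
  for (run in seq_len(n_runs)) {
    set.seed(seed + run - 1)
    ia <- sample.int(nrow(A)); ib <- sample.int(nrow(B))
    na_tr <- floor(train_frac * nrow(A)); nb_tr <- floor(train_frac * nrow(B))
    if (na_tr < 1 || nb_tr < 1 || na_tr >= nrow(A) || nb_tr >= nrow(B))
      se_stop("a class would be absent from a split",
              class = "synexpr_stratification_error")
    Atr <- A[ia[seq_len(na_tr)], , drop = FALSE]
    Ate <- A[ia[-seq_len(na_tr)], , drop = FALSE]
    Btr <- B[ib[seq_len(nb_tr)], , drop = FALSE]
    Bte <- B[ib[-seq_len(nb_tr)], , drop = FALSE]
    if (space == "pc") {
      k <- min(n_pc, nrow(Atr) - 1, ncol(Atr))
      pc <- prcomp(Atr, center = TRUE, scale. = FALSE)
      proj <- function(M) predict(pc, M)[, seq_len(k), drop = FALSE]
      Atr <- proj(Atr); Ate <- proj(Ate); Btr <- proj(Btr); Bte <- proj(Bte)
    }
    Xtr <- rbind(Atr, Btr); ytr <- c(rep("real", nrow(Atr)),
                                     rep("synthetic", nrow(Btr)))
    Xte <- rbind(Ate, Bte); yte <- c(rep("real", nrow(Ate)),
                                     rep("synthetic", nrow(Bte)))
    for (cl in classifiers) {
      fit <- fit_classifier(cl, Xtr, ytr, seed = seed + run - 1)
      pred <- predict_classifier(fit, Xte)
      out[[length(out) + 1]] <- tibble::tibble(
        classifier = cl, space = space, run = run,
        f1 = binary_f1(yte, as.character(pred), positive = "real"))
    }
  }
  dplyr::bind_rows(out)
}

#' Train-on-synthetic, test-on-real utility
#'
#' Fits multi-class classifiers on synthetic samples with synthetic labels
#' and scores them on held-out real data, reporting balanced accuracy (mean
#' per-class recall) and macro-averaged F1 — the equal-class-weight metrics
#' appropriate for the strongly imbalanced covariates these models condition
#' on. Real-test classes absent from the synthetic labels are reported in the
#' `missing_classes` attribute.
#'
#' @param X_syn,y_syn synthetic training data and labels.
#' @param X_real_test,y_real_test real held-out data and labels.
#' @param classifiers subset of `c("lr", "mlp", "knn")`.
#' @param seed RNG seed.
#' @return tibble with one row per classifier: balanced accuracy and macro F1.
#' @export
tstr <- function(X_syn, y_syn, X_real_test, y_real_test,
                 classifiers = c("lr", "mlp", "knn"), seed = 1) {
  Xs <- as_expr_values(X_syn); Xr <- as_expr_values(X_real_test)
  y_syn <- as.character(y_syn); y_real <- as.character(y_real_test)
  if (length(unique(y_syn)) < 2)
    se_stop("synthetic labels contain a single class; training is degenerate",
            class = "synexpr_degenerate_error")
  missing_cl <- setdiff(unique(y_real), unique(y_syn))
  rows <- lapply(classifiers, function(cl) {
    fit <- fit_classifier(cl, Xs, y_syn, seed = seed)
    pred <- as.character(predict_classifier(fit, Xr))
    tibble::tibble(classifier = cl,
                   balanced_accuracy = balanced_accuracy(y_real, pred),
                   macro_f1 = macro_f1(y_real, pred))
  })
  res <- dplyr::bind_rows(rows)
  attr(res, "missing_classes") <- missing_cl
  res
}

#' Per-gene two-sample Kolmogorov-Smirnov tests
#'
#' @param X_real,X_syn matrices or [expression_matrix()]s with aligned genes.
#' @param adjust multiple-testing adjustment (default Benjamini-Hochberg).
#' @return tibble of gene, statistic, p, p_adjusted.
#' @export
ks_per_gene <- function(X_real, X_syn, adjust = "BH") {
  A <- as_expr_values(X_real); B <- as_expr_values(X_syn)
  if (nrow(A) < 2 || nrow(B) < 2) se_stop("need >= 2 samples per set")
  res <- lapply(seq_len(ncol(A)), function(j) {
    kt <- suppressWarnings(ks.test(A[, j], B[, j], exact = FALSE))
    tibble::tibble(gene = colnames(A)[j], statistic = unname(kt$statistic),
                   p = kt$p.value)
  })
  out <- dplyr::bind_rows(res)
  out$p_adjusted <- p.adjust(out$p, method = adjust)
  out
}

# exact p-Wasserstein distance between two 1-D empirical distributions via
# the quantile-function formula integrated over the merged breakpoints
wasserstein_1d <- function(x, y, p = 2) {
  xs <- sort(x); ys <- sort(y)
  n <- length(xs); m <- length(ys)
  br <- sort(unique(c(seq_len(n) / n, seq_len(m) / m)))
  lo <- c(0, head(br, -1))
  mid <- (lo + br) / 2
  qx <- xs[ceiling(mid * n)]
  qy <- ys[ceiling(mid * m)]
  (sum((br - lo) * abs(qx - qy)^p))^(1 / p)
}

#' Mean per-gene Wasserstein distance
#'
#' The p-Wasserstein distance between the two empirical marginal
#' distributions of each gene (exact quantile-matching formula), averaged
#' over genes. Order 2 by default, matching the WD2 curve metric.
#'
#' @param X_real,X_syn matrices or [expression_matrix()]s with aligned genes.
#' @param order Wasserstein order p.
#' @return nonnegative scalar.
#' @export
mean_gene_wasserstein <- function(X_real, X_syn, order = 2) {
  A <- as_expr_values(X_real); B <- as_expr_values(X_syn)
  if (!nrow(A) || !nrow(B)) se_stop("need >= 1 sample per set")
  mean(vapply(seq_len(ncol(A)),
              function(j) wasserstein_1d(A[, j], B[, j], order),
              numeric(1)))
}

#' Run the full evaluation suite
#'
#' Computes manifold precision/recall, the correlation-preservation
#' coefficient, detectability in full-feature and PC space, TSTR utility
#' (when synthetic covariates are available), per-gene KS tests and mean
#' per-gene Wasserstein distance, all under one base seed. Operates in the
#' space the matrices are given in (normalized training space by default).
#'
#' @param X_real,X_syn aligned expression matrices.
#' @param C_real,C_syn optional covariate tables; TSTR uses `label_covariate`
#'   from them (trained on synthetic, tested on a held-out 30% of the real
#'   samples) and is skipped with a marker when `C_syn` is `NULL`.
#' @param t neighbour order for precision/recall.
#' @param classifiers classifier families for detectability/TSTR.
#' @param n_runs detectability repetitions (10 to match the reporting
#'   protocol; reduce for quick checks).
#' @param n_pc principal components for PC-space detectability.
#' @param label_covariate covariate name used as the TSTR label (defaults to
#'   the first covariate).
#' @param seed base seed shared by all stochastic metrics.
#' @return object of class `evaluation_report`.
#' @export
evaluate_all <- function(X_real, X_syn, C_real = NULL, C_syn = NULL,
                         t = 10, classifiers = c("lr", "mlp", "knn"),
                         n_runs = 10, n_pc = 100, label_covariate = NULL,
                         seed = 1) {
  A <- as_expr_values(X_real); B <- as_expr_values(X_syn)
  if (!identical(colnames(A), colnames(B)))
    se_stop("gene orders differ between real and synthetic matrices",
            class = "synexpr_validation_error")
  pr <- precision_recall(A, B, t = t)
  cc <- correlation_coefficient(A, B)
  det_full <- detectability(A, B, classifiers, "full", n_pc, n_runs,
                            seed = seed)
  det_pc <- detectability(A, B, classifiers, "pc", n_pc, n_runs, seed = seed)
  ks <- ks_per_gene(A, B)
  wd <- mean_gene_wasserstein(A, B)
  tstr_res <- NULL; tstr_skipped <- TRUE
  if (!is.null(C_syn) && !is.null(C_real)) {
    if (is.null(label_covariate))
      label_covariate <- covariate_names(C_real)[1]
    set.seed(seed)
    n_te <- max(1, floor(0.3 * nrow(A)))
    te <- sample.int(nrow(A), n_te)
    y_syn <- as.character(C_syn[[label_covariate]])
    if (length(unique(y_syn)) >= 2) {
      tstr_res <- tstr(B, y_syn, A[te, , drop = FALSE],
                       as.character(C_real[[label_covariate]])[te],
                       classifiers, seed = seed)
      tstr_skipped <- FALSE
    }
  }
  structure(list(
    precision = pr$precision, recall = pr$recall,
    correlation_coefficient = cc,
    detectability = dplyr::bind_rows(det_full, det_pc),
    tstr = tstr_res, tstr_skipped = tstr_skipped,
    ks = ks, mean_gene_wasserstein = wd,
    meta = list(t = t, seed = seed, n_runs = n_runs, n_pc = n_pc,
                classifiers = classifiers,
                label_covariate = label_covariate,
                n_real = nrow(A), n_syn = nrow(B), n_genes = ncol(A))),
    class = "evaluation_report")
}

#' @method print evaluation_report
#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  precision %.3f  recall %.3f  correlation %.3f  WD%d %.4f\n",
              x$precision, x$recall, x$correlation_coefficient, 2,
              x$mean_gene_wasserstein))
  det <- x$detectability %>% dplyr::group_by(.data$classifier, .data$space) %>%
    dplyr::summarise(f1 = mean(.data$f1), .groups = "drop")
  for (i in seq_len(nrow(det)))
    cat(sprintf("  detectability F1 [%s, %s] %.3f\n", det$classifier[i],
                det$space[i], det$f1[i]))
  if (x$tstr_skipped) cat("  TSTR: skipped (no synthetic covariates)\n")
  else for (i in seq_len(nrow(x$tstr)))
    cat(sprintf("  TSTR [%s] balanced acc %.3f  macro F1 %.3f\n",
                x$tstr$classifier[i], x$tstr$balanced_accuracy[i],
                x$tstr$macro_f1[i]))
  cat(sprintf("  KS: %d/%d genes with adjusted p < 0.05\n",
              sum(x$ks$p_adjusted < 0.05), nrow(x$ks)))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the scalar metrics plus metadata as JSON and the per-gene KS table
#' as TSV (`<path>.genes.tsv`).
#' @param report an `evaluation_report`.
#' @param path JSON output path.
#' @export
write_evaluation_report <- function(report, path) {
  det <- report$detectability %>%
    dplyr::group_by(.data$classifier, .data$space) %>%
    dplyr::summarise(f1 = mean(.data$f1), .groups = "drop")
  obj <- list(precision = report$precision, recall = report$recall,
              correlation_coefficient = report$correlation_coefficient,
              mean_gene_wasserstein = report$mean_gene_wasserstein,
              detectability = det,
              tstr = report$tstr, tstr_skipped = report$tstr_skipped,
              meta = report$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  readr::write_tsv(report$ks, paste0(path, ".genes.tsv"), progress = FALSE)
  invisible(path)
}
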