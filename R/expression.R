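#' Expression matrix container
#'
#' A thin S3 container for a samples-by-genes matrix of continuous expression
#' values, together with a tag recording which space the values live in:
#' `"raw"` (as loaded), `"minmax01"` (per-gene min-max scaled to \[0, 1\]) or
#' `"log2_zscore"` (log2 then per-gene standard scaling).
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param sample_ids character vector of unique sample identifiers (rows).
#' @param space one of `"raw"`, `"minmax01"`, `"log2_zscore"`.
#'
#' @return an object of class `expr_mat`.
#' @export
expression_matrix <- function(values, gene_ids = colnames(values),
                              sample_ids = rownames(values),
                              space = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  space <- match.arg(space, c("raw", "minmax01", "log2_zscore"))
  if (length(gene_ids) != ncol(values))
    se_stop("`gene_ids` length must equal the number of columns")
  if (length(sample_ids) != nrow(values))
    se_stop("`sample_ids` length must equal the number of rows")
  if (anyDuplicated(gene_ids))
    se_stop(paste0("duplicate gene identifiers: ",
                   paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")),
            class = "synexpr_validation_error")
  if (anyDuplicated(sample_ids))
    se_stop(paste0("duplicate sample identifiers: ",
                   paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")),
            class = "synexpr_validation_error")
  if (space != "raw" && anyNA(values))
    se_stop("normalized expression matrices must not contain missing values")
  if (space == "minmax01" &&
      any(values < -1e-9 | values > 1 + 1e-9, na.rm = TRUE))
    se_stop("space 'minmax01' requires all values within [0, 1] (tol 1e-9)")
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, space = space),
            class = "expr_mat")
}

#' @method print expr_mat
#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d samples x %d genes, space = %s\n",
              nrow(x$values), ncol(x$values), x$space))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param x an `expr_mat`.
#' @export
n_genes <- function(x) UseMethod("n_genes")
#' @export
n_genes.expr_mat <- function(x) ncol(x$values)
#' @export
n_genes.gene_graph <- function(x) length(x$gene_ids)

#' @rdname expression_matrix
#' @export
n_samples <- function(x) UseMethod("n_samples")
#' @export
n_samples.expr_mat <- function(x) nrow(x$values)

#' @method as.matrix expr_mat
#' @export
as.matrix.expr_mat <- function(x, ...) x$values

# coerce matrix-or-expr_mat arguments
as_expr_values <- function(x) {
  if (inherits(x, "expr_mat")) x$values else as.matrix(x)
}

#' @export
as_tibble.expr_mat <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "sample_id")
}

#' Read and write expression tables
#'
#' Delimited text (tab for `.tsv`/`.txt`, comma for `.csv`) with one header row
#' of column identifiers and one leading column of row identifiers. The result
#' is always returned in samples-by-genes orientation.
#'
#' @param path file path.
#' @param orientation whether the file stores samples in rows
#'   (`"samples_by_genes"`) or genes in rows (`"genes_by_samples"`).
#' @return an [expression_matrix()] with `space = "raw"`.
#' @export
read_expression_table <- function(path,
                                  orientation = c("samples_by_genes",
                                                  "genes_by_samples")) {
  orientation <- match.arg(orientation)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    show_col_types = FALSE)
  if (ncol(raw) < 2) se_stop("expression table needs a row-id column plus data")
  row_ids <- as.character(raw[[1]])
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    se_stop(sprintf(
      "non-numeric cell '%s' at row '%s', column '%s'",
      body[bad[1], bad[2]], row_ids[bad[1]], colnames(raw)[-1][bad[2]]),
      class = "synexpr_parse_error")
  }
  dimnames(num) <- list(row_ids, colnames(raw)[-1])
  if (orientation == "genes_by_samples") num <- t(num)
  expression_matrix(num, space = "raw")
}

#' @rdname read_expression_table
#' @param X an `expr_mat`.
#' @export
write_expression_table <- function(X, path,
                                   orientation = c("samples_by_genes",
                                                   "genes_by_samples")) {
  orientation <- match.arg(orientation)
  m <- X$values
  if (orientation == "genes_by_samples") m <- t(m)
  df <- tibble::as_tibble(m, rownames = "id")
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Per-sample categorical covariates
#'
#' Stores one category per sample per covariate. Missing values (NA or empty
#' strings) are mapped to an explicit `"MISSING"` category, mirroring how
#' unannotated experimental conditions are treated as their own class.
#'
#' @param df data frame with a `sample_id` column and one column per covariate.
#' @param missing_label category used for missing values.
#' @return an object of class `cov_table`: a tibble of factors plus a
#'   `vocabularies` attribute (named list of category levels per covariate).
#' @export
covariate_table <- function(df, missing_label = "MISSING") {
  df <- tibble::as_tibble(df)
  if (!"sample_id" %in% names(df)) se_stop("`df` needs a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    se_stop("duplicate sample identifiers in covariate table",
            class = "synexpr_validation_error")
  covs <- setdiff(names(df), "sample_id")
  if (!length(covs)) se_stop("covariate table has no covariate columns")
  for (v in covs) {
    x <- as.character(df[[v]])
    x[is.na(x) | x == ""] <- missing_label
    lev <- sort(unique(x))
    df[[v]] <- factor(x, levels = lev)
  }
  df$sample_id <- as.character(df$sample_id)
  structure(df, class = c("cov_table", class(tibble::tibble())))
}

#' @method print cov_table
#' @export
print.cov_table <- function(x, ...) {
  cat(sprintf("<cov_table> %d samples, covariates: %s\n", nrow(x),
              paste(covariate_names(x), collapse = ", ")))
  NextMethod()
}

#' @rdname covariate_table
#' @param ct a `cov_table`.
#' @export
covariate_names <- function(ct) setdiff(names(ct), "sample_id")

#' @rdname covariate_table
#' @export
vocabularies <- function(ct) {
  lapply(ct[covariate_names(ct)], levels)
}

#' @rdname covariate_table
#' @param path file path of a delimited covariate table (sample_id + one
#'   column per covariate).
#' @export
read_covariate_table <- function(path, missing_label = "MISSING") {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    show_col_types = FALSE)
  names(df)[1] <- "sample_id"
  covariate_table(df, missing_label = missing_label)
}

#' @rdname covariate_table
#' @export
write_covariate_table <- function(ct, path) {
  out <- tibble::as_tibble(lapply(ct, as.character))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

# integer codes (1-based) for each covariate, aligned to vocabularies()
covariate_codes <- function(ct) {
  covs <- covariate_names(ct)
  m <- vapply(covs, function(v) as.integer(ct[[v]]), integer(nrow(ct)))
  m <- matrix(m, nrow = nrow(ct), dimnames = list(ct$sample_id, covs))
  m
}
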