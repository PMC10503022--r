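# Single-cell front end: count-matrix ingestion, log1p normalization,
# highly-variable-gene selection and the cluster x condition abundance table.

#' Read a single-cell count matrix
#'
#' Reads a count matrix from MatrixMarket coordinate format (with plain-text
#' row/column name sidecars, one name per line) or from dense CSV/TSV with a
#' header row and a leading name column. Single-cell files commonly arrive
#' genes x cells; set `transpose = TRUE` to flip them so that cells are rows,
#' the orientation every downstream function expects. Sparse input stays
#' sparse.
#'
#' @param path matrix file (.mtx, .csv or .tsv).
#' @param format `"auto"` (by extension), `"mtx"`, `"csv"` or `"tsv"`.
#' @param transpose flip the matrix after reading.
#' @param row_names,col_names sidecar paths with the names of the file's rows
#'   and columns (before any transpose); used for MTX input.
#' @return A `count_matrix` (subclass of [data_matrix()]) with cells as rows.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                        transpose = FALSE, row_names = NULL, col_names = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv",
                     stop(sprintf("cannot infer format from extension '%s'", ext)))
  }
  if (format == "mtx") {
    v <- methods::as(methods::as(Matrix::readMM(path), "CsparseMatrix"), "generalMatrix")
    rn <- read_name_sidecar(row_names, nrow(v), "row")
    cn <- read_name_sidecar(col_names, ncol(v), "column")
    dimnames(v) <- list(rn, cn)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE)
    v <- as.matrix(df)
    storage.mode(v) <- "double"
  }
  if (isTRUE(transpose)) v <- Matrix::t(v)
  as_count_matrix(v)
}

read_name_sidecar <- function(path, expected, axis) {
  if (is.null(path)) return(NULL)
  nm <- readLines(path)
  if (length(nm) != expected)
    stop(sprintf("%s-name sidecar '%s' has %d lines but the matrix has %d %ss",
                 axis, path, length(nm), expected, axis), call. = FALSE)
  nm
}

as_count_matrix <- function(v) {
  neg <- if (inherits(v, "sparseMatrix")) any(v@x < 0) else any(v < 0)
  if (neg) stop("count matrices must be non-negative", call. = FALSE)
  check_unique_names(rownames(v), "cell")
  check_unique_names(colnames(v), "gene")
  out <- data_matrix(v, value_type = "float64")
  class(out) <- c("count_matrix", class(out))
  out
}

check_unique_names <- function(nm, what) {
  if (!is.null(nm) && anyDuplicated(nm))
    stop(sprintf("%s names must be unique", what), call. = FALSE)
}

#' Write a count matrix to MTX or CSV
#'
#' Companion writer to [read_counts()]: MatrixMarket coordinate format plus
#' `<path>.rownames` / `<path>.colnames` sidecars for sparse matrices, or a
#' dense CSV with header and leading name column.
#'
#' @param x a `count_matrix` or [data_matrix()].
#' @param path destination; `.mtx` or `.csv` decides the format.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  v <- if (inherits(x, "data_matrix")) x$values else x
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(methods::as(v, "CsparseMatrix"), path)
    if (!is.null(rownames(v)))
      writeLines(rownames(v), paste0(path, ".rownames"))
    if (!is.null(colnames(v)))
      writeLines(colnames(v), paste0(path, ".colnames"))
  } else if (ext == "csv") {
    m <- as.matrix(v)
    df <- data.frame(name = rownames(m) %||% paste0("r", seq_len(nrow(m))),
                     m, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else stop(sprintf("unsupported extension '%s' (use .mtx or .csv)", ext))
  invisible(path)
}

#' Log1p normalization
#'
#' Replaces every count c by log(c + 1). Zeros map to zeros, so the sparsity
#' pattern is preserved and sparse matrices stay sparse. This is the only
#' normalization applied; per-cell depth scaling is deliberately not
#' performed.
#'
#' @param x a `count_matrix` or [data_matrix()].
#' @return A [data_matrix()] of normalized values.
#' @export
lognorm <- function(x) {
  v <- if (inherits(x, "data_matrix")) x$values else x
  if (inherits(v, "sparseMatrix")) {
    v@x <- log1p(v@x)
  } else {
    v <- log1p(as.matrix(v))
  }
  data_matrix(v, value_type = "float64", comment = "log1p-normalized")
}

#' Select highly variable genes
#'
#' Keeps the `n_genes` columns with the highest sample variance (computed on
#' the values as given, typically after [lognorm()]). Ties break to the lower
#' column index; the surviving columns keep their original order and names.
#'
#' @param x a [data_matrix()] (dense or sparse), cells x genes.
#' @param n_genes number of genes to keep, at most `ncol(x)`.
#' @return A [data_matrix()] with `n_genes` columns.
#' @export
select_hvg <- function(x, n_genes) {
  v <- if (inherits(x, "data_matrix")) x$values else x
  d <- ncol(v)
  n <- nrow(v)
  n_genes <- as.integer(n_genes)
  if (n_genes > d)
    stop(sprintf("n_genes = %d exceeds the %d available genes", n_genes, d))
  if (inherits(v, "sparseMatrix")) {
    mu <- Matrix::colSums(v) / n
    vars <- (Matrix::colSums(v^2) - n * mu^2) / (n - 1)
  } else {
    mu <- colMeans(v)
    vars <- (colSums(v^2) - n * mu^2) / (n - 1)
  }
  keep <- sort(order(-vars, seq_len(d))[seq_len(n_genes)])
  out <- data_matrix(v[, keep, drop = FALSE],
                     value_type = if (inherits(x, "data_matrix")) x$value_type else "float64")
  out
}

#' Cluster-by-condition abundance matrix
#'
#' Cross-tabulates cells by cluster and experimental condition: entry (c, g)
#' counts the cells assigned to cluster c that carry condition label g, and
#' the companion proportions table row-normalizes those counts. Condition
#' columns appear in order of first appearance.
#'
#' @param assignment an `scpam` fit or a vector of cluster labels, one per
#'   cell.
#' @param conditions a vector of condition labels, one per cell.
#' @return An `abundance_matrix`: list with integer matrix `counts`,
#'   row-normalized `proportions`, `cluster_ids`, `condition_labels`.
#' @export
#' @examples
#' ab <- build_abundance(c(1, 1, 1, 2, 2, 2), c("g1", "g1", "g2", "g2", "g2", "g2"))
#' ab$counts
build_abundance <- function(assignment, conditions) {
  if (inherits(assignment, "scpam")) assignment <- assignment$assignment
  if (length(assignment) != length(conditions))
    stop(sprintf("assignment (%d) and conditions (%d) lengths differ",
                 length(assignment), length(conditions)))
  conditions <- as.character(conditions)
  cond_levels <- unique(conditions) # first-appearance order
  clus_levels <- sort(unique(assignment))
  counts <- table(factor(assignment, levels = clus_levels),
                  factor(conditions, levels = cond_levels))
  counts <- matrix(as.integer(counts), nrow = length(clus_levels),
                   dimnames = list(as.character(clus_levels), cond_levels))
  proportions <- counts / rowSums(counts)
  structure(list(counts = counts, proportions = proportions,
                 cluster_ids = clus_levels, condition_labels = cond_levels),
            class = "abundance_matrix")
}

#' @export
#' @method print abundance_matrix
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance matrix: %d clusters x %d conditions, %d cells\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  print(x$counts)
  invisible(x)
}
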