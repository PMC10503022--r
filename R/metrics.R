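# Pairwise dissimilarities between the rows of a data matrix.

METRICS <- c(L1 = 0L, L2 = 1L, pearson = 2L, cosine = 3L, weighted_euclidean = 4L)

#' Pairwise dissimilarity matrix between individuals
#'
#' Computes the full symmetric matrix of pairwise dissimilarities between the
#' rows (individuals/cells) of a data matrix, in parallel, for one of five
#' metrics:
#'
#' * `L1` — Manhattan / city block, \eqn{\sum_f |x_{if} - x_{jf}|}
#' * `L2` — Euclidean, \eqn{\sqrt{\sum_f (x_{if} - x_{jf})^2}}
#' * `weighted_euclidean` — \eqn{\sqrt{\sum_f w_f (x_{if} - x_{jf})^2}} with
#'   user-supplied non-negative feature weights
#' * `pearson` — \eqn{1 - r(x_i, x_j)}, one minus the sample Pearson
#'   correlation across features (range \eqn{[0, 2]})
#' * `cosine` — \eqn{1 - x_i \cdot x_j / (\|x_i\| \|x_j\|)}
#'
#' Sparse input takes a fast path whose inner loop visits only the union of
#' the two rows' nonzero feature sets (plus O(1) per-row precomputed sums,
#' sums of squares and norms for the correlation/cosine cross terms), so
#' zero-zero feature pairs are never touched. With `dtype = "float32"` all
#' per-entry arithmetic is done in single precision, emulating a float-typed
#' dissimilarity matrix at half the memory.
#'
#' Results are bitwise identical for any `workers` count: every matrix entry
#' is computed independently over a static partition of the index space.
#'
#' @param x a [data_matrix()] (dense or sparse), or a plain matrix /
#'   `dgCMatrix`; rows are individuals, columns features. Use the transpose
#'   option of [read_counts()] if your data arrive genes x cells.
#' @param metric one of `"L1"`, `"L2"`, `"pearson"`, `"cosine"`,
#'   `"weighted_euclidean"`.
#' @param weights non-negative numeric vector, one weight per feature;
#'   required for (and only for) `weighted_euclidean`.
#' @param dtype `"float64"` (default) or `"float32"`.
#' @param workers number of parallel workers (threads).
#' @return A `dissimilarity_matrix` (subclass of [symmetric_matrix()]) with
#'   zero diagonal, tagged with the metric name.
#' @export
#' @examples
#' X <- make_line_fixture()
#' D <- pairwise_dissimilarity(X, "L1")
#' as.matrix(D)[1, 6] # |0 - 12| = 12
pairwise_dissimilarity <- function(x, metric = c("L2", "L1", "pearson", "cosine",
                                                 "weighted_euclidean"),
                                   weights = NULL,
                                   dtype = c("float64", "float32"),
                                   workers = 1L) {
  metric <- match.arg(metric)
  dtype <- match.arg(dtype)
  workers <- check_workers(workers)
  if (inherits(x, "data_matrix")) v <- x$values else v <- x
  sparse <- inherits(v, "sparseMatrix")
  if (!sparse) {
    v <- as.matrix(v)
    storage.mode(v) <- "double"
  } else {
    v <- methods::as(methods::as(v, "CsparseMatrix"), "generalMatrix")
  }
  n <- nrow(v)
  d <- ncol(v)
  if (n < 2) stop("need at least 2 individuals (rows)")
  if (d < 1) stop("need at least 1 feature (column)")
  if (metric == "weighted_euclidean") {
    if (is.null(weights))
      stop("metric 'weighted_euclidean' requires a weights vector")
    if (length(weights) != d)
      stop(sprintf("weights length %d does not match %d features",
                   length(weights), d))
    if (any(weights < 0)) stop("weights must be non-negative")
    weights <- as.double(weights)
  } else {
    if (!is.null(weights))
      stop(sprintf("weights are only accepted for metric 'weighted_euclidean', not '%s'", metric))
    weights <- double(0)
  }
  if (metric == "pearson" && d < 2)
    stop("metric 'pearson' needs at least 2 features")

  # degenerate rows are hard errors: NaN entries would silently poison PAM
  if (metric %in% c("pearson", "cosine")) {
    if (sparse) {
      sx <- Matrix::rowSums(v)
      sxx <- Matrix::rowSums(v^2)
    } else {
      sx <- rowSums(v)
      sxx <- rowSums(v^2)
    }
    if (metric == "cosine") {
      bad <- which(sxx == 0)
      if (length(bad))
        stop(sprintf("row %s has zero norm; cosine dissimilarity is undefined",
                     row_label(v, bad[1])), call. = FALSE)
    } else {
      bad <- which(d * sxx - sx^2 <= 0)
      if (length(bad))
        stop(sprintf("row %s has zero variance; Pearson dissimilarity is undefined",
                     row_label(v, bad[1])), call. = FALSE)
    }
  }

  mcode <- METRICS[[metric]]
  f32 <- dtype == "float32"
  if (sparse) {
    tv <- methods::as(Matrix::t(v), "CsparseMatrix") # CSR view of v
    D <- cpp_pairwise_sparse(tv@p, tv@i, tv@x, n, d, mcode, weights, f32, workers)
  } else {
    D <- cpp_pairwise_dense(v, mcode, weights, f32, workers)
  }
  dimnames(D) <- list(rownames(v), rownames(v))
  out <- symmetric_matrix(D, value_type = dtype,
                          comment = paste0("metric=", metric))
  as_dissimilarity(out, metric)
}

as_dissimilarity <- function(sym, metric) {
  sym$metric <- metric
  class(sym) <- c("dissimilarity_matrix", class(sym))
  sym
}

#' @export
#' @method print dissimilarity_matrix
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("<dissimilarity_matrix> %d individuals, metric %s, value type %s\n",
              nrow(x$values), x$metric %||% "?", x$value_type))
  invisible(x)
}

row_label <- function(v, i) {
  if (!is.null(rownames(v))) sprintf("%d ('%s')", i, rownames(v)[i]) else as.character(i)
}

check_workers <- function(workers) {
  workers <- as.integer(workers)
  if (length(workers) != 1L || is.na(workers) || workers < 1L)
    stop("workers must be a positive integer")
  workers
}

# coerce anything dissimilarity-like to a plain dense symmetric double matrix
as_diss_values <- function(D) {
  if (inherits(D, "symmetric_matrix")) return(D$values)
  if (inherits(D, "dist")) return(as.matrix(D))
  if (is.matrix(D)) {
    storage.mode(D) <- "double"
    return(D)
  }
  stop("expected a dissimilarity_matrix, symmetric_matrix, dist or square matrix")
}
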