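# Deterministic generators for synthetic test data.

#' Six-point line fixture
#'
#' The canonical 1-D instance X = (0, 1, 2, 10, 11, 12), points p0..p5: two
#' obvious groups of three whose k = 2 medoid optimum (values 1 and 11,
#' TD = 4 under L1) is verifiable by exhaustive search over all 15 medoid
#' pairs.
#'
#' @return A 6 x 1 [data_matrix()].
#' @export
make_line_fixture <- function() {
  v <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1,
              dimnames = list(paste0("p", 0:5), "x"))
  data_matrix(v, value_type = "float64")
}

#' Planted Gaussian blobs
#'
#' Isotropic Gaussian clusters around given centers, for parameter-recovery
#' tests: with separation/sigma large, any sane clustering method must
#' recover the planted partition.
#'
#' @param n_per_cluster points per cluster.
#' @param centers numeric matrix, one center per row.
#' @param sigma standard deviation of the isotropic noise.
#' @param seed random seed; the output is a pure function of the arguments.
#' @return List with `data` (a [data_matrix()], rows grouped by cluster),
#'   `labels` (planted cluster id per row) and `separation_ratio` (smallest
#'   pairwise center distance divided by `sigma`).
#' @export
make_blobs <- function(n_per_cluster, centers, sigma, seed = 1L) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  d <- ncol(centers)
  n <- n_per_cluster * k
  X <- with_seed(seed,
    centers[rep(seq_len(k), each = n_per_cluster), , drop = FALSE] +
      matrix(stats::rnorm(n * d, sd = sigma), n, d))
  dimnames(X) <- list(paste0("obs", seq_len(n)), paste0("f", seq_len(d)))
  cd <- as.matrix(stats::dist(centers))
  sep <- if (k > 1) min(cd[upper.tri(cd)]) / sigma else Inf
  list(data = data_matrix(X, value_type = "float64"),
       labels = rep(seq_len(k), each = n_per_cluster),
       separation_ratio = sep)
}

#' Sparse synthetic count matrix
#'
#' Emulates the sparsity structure of a single-cell count matrix: `density`
#' of the entries are nonzero, positions uniform at random, and each nonzero
#' value is Poisson(`rate`) + 1 so the declared sparsity pattern is exact.
#' No attempt is made to mimic gene-wise dispersion or library-size effects;
#' this is a structural fixture, not a realistic scRNA simulator.
#'
#' @param n_cells,n_genes dimensions.
#' @param density fraction of nonzero entries, in (0, 1].
#' @param rate mean of the Poisson part of the nonzero counts.
#' @param seed random seed.
#' @return A sparse `count_matrix` with names cell1.., gene1..
#' @export
make_sparse_counts <- function(n_cells, n_genes, density = 0.1, rate = 5,
                               seed = 1L) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  nnz <- round(density * n_cells * n_genes)
  with_seed(seed, {
    pos <- sample.int(n_cells * n_genes, nnz)
    vals <- stats::rpois(nnz, rate) + 1
    v <- Matrix::sparseMatrix(i = ((pos - 1L) %% n_cells) + 1L,
                              j = ((pos - 1L) %/% n_cells) + 1L,
                              x = as.double(vals),
                              dims = c(n_cells, n_genes))
    dimnames(v) <- list(paste0("cell", seq_len(n_cells)),
                        paste0("gene", seq_len(n_genes)))
    as_count_matrix(v)
  })
}
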