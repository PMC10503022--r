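# Silhouette widths from a dissimilarity matrix and a cluster assignment.

#' Silhouette widths of a clustering
#'
#' For point i in cluster C, with a(i) the mean dissimilarity to the other
#' members of C and b(i) the smallest mean dissimilarity to the members of
#' any other cluster, the silhouette width is
#' \deqn{s(i) = \frac{b(i) - a(i)}{\max(a(i), b(i))} \in [-1, 1].}
#' Points alone in their cluster score 0 by convention (Rousseeuw). The mean
#' silhouette width over all points is a standard measure of clustering
#' quality and a guide for choosing the number of clusters k. A single
#' cluster is an error: b(i) is undefined with no other cluster, and a silent
#' all-zero answer would mislead k selection.
#'
#' The computation is a dense matrix product over cluster indicators; its
#' result does not depend on `workers`.
#'
#' @param D a dissimilarity matrix (any form accepted by [scpam()]).
#' @param assignment an `scpam` fit or an integer vector of cluster ids in
#'   `1..k`; every id must occur at least once.
#' @param workers accepted for interface symmetry; the result is identical
#'   for any value.
#' @return An object of class `scpam_silhouette`: list with `s` (per-point
#'   widths), `cluster_means`, `overall_mean`, `assignment`.
#' @export
#' @examples
#' D <- pairwise_dissimilarity(make_line_fixture(), "L1")
#' sw <- silhouette_width(D, rep(1:2, each = 3))
#' sw$overall_mean
silhouette_width <- function(D, assignment, workers = 1L) {
  check_workers(workers)
  dv <- as_diss_values(D)
  n <- nrow(dv)
  if (inherits(assignment, "scpam")) assignment <- assignment$assignment
  assignment <- as.integer(assignment)
  if (length(assignment) != n)
    stop(sprintf("assignment length %d does not match the %d x %d dissimilarity matrix",
                 length(assignment), n, n))
  k <- max(assignment)
  if (any(assignment < 1L))
    stop("cluster ids must be positive integers")
  sizes <- tabulate(assignment, nbins = k)
  if (any(sizes == 0L))
    stop(sprintf("cluster id %d is empty: every id in 1..k must be used",
                 which(sizes == 0L)[1]))
  if (k < 2L)
    stop("silhouette is undefined for a single cluster (k must be >= 2)")

  Z <- matrix(0, n, k)
  Z[cbind(seq_len(n), assignment)] <- 1
  sums <- dv %*% Z                       # sums[i, c] = sum_{j in c} D(i, j)
  own <- cbind(seq_len(n), assignment)
  a <- sums[own] / (sizes[assignment] - 1)
  means_other <- sweep(sums, 2, sizes, "/")
  means_other[own] <- Inf
  b <- apply(means_other, 1, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[assignment] == 1L] <- 0        # singleton convention
  names(s) <- rownames(dv)
  cluster_means <- as.vector(tapply(s, assignment, mean))
  structure(list(s = s, cluster_means = cluster_means,
                 overall_mean = mean(s), assignment = assignment,
                 k = k), class = "scpam_silhouette")
}

#' @export
#' @method print scpam_silhouette
print.scpam_silhouette <- function(x, ...) {
  cat(sprintf("silhouette of %d points in %d clusters\n", length(x$s), x$k))
  cat("per-cluster means:", paste(signif(x$cluster_means, 4), collapse = ", "), "\n")
  cat("overall mean:", signif(x$overall_mean, 6), "\n")
  invisible(x)
}
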