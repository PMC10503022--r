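# PAM (k-medoids): BUILD / LAB initialization and the FASTPAM1 swap phase.

#' k-medoids clustering with FASTPAM1
#'
#' Partitioning around medoids on a precomputed dissimilarity matrix. The
#' objective is the total deviation
#' \deqn{TD = \sum_{i=1}^{k} \sum_{x_c \in C_i} d(x_c, m_i),}
#' the sum of dissimilarities of every point to the medoid of its cluster,
#' where a medoid is the cluster member with the smallest sum of
#' dissimilarities to all other members. Initial medoids come from the
#' deterministic greedy BUILD method or its randomized subsample variant LAB;
#' the swap phase uses FASTPAM1, which evaluates the TD change of all k
#' possible swaps for one entering candidate in a single pass over the points
#' using cached nearest and second-nearest medoid distances. Per iteration the
#' single best strictly improving swap is applied; ties break to the lowest
#' (candidate, medoid slot) pair, so results are fully deterministic and
#' independent of the worker count.
#'
#' @param D a `dissimilarity_matrix` from [pairwise_dissimilarity()], a
#'   [symmetric_matrix()], a [stats::dist] object or a square symmetric
#'   matrix.
#' @param k number of medoids, `2 <= k < n`.
#' @param init `"build"` (deterministic) or `"lab"` (randomized subsample).
#' @param seed random seed, used by LAB only; ignored for BUILD.
#' @param max_iter cap on swap iterations; `0` returns the initialization
#'   clustering unchanged.
#' @param workers number of parallel workers for the swap phase. The result
#'   is bitwise identical for any value.
#' @return An object of class `scpam`: a list with `medoids` (indices into
#'   the rows of `D`), `medoid_names`, `assignment` (cluster id in `1..k` per
#'   point, named), `td`, `n_swaps`, `iterations`, `converged`, `td_trace`
#'   (TD after initialization and after each applied swap), `applied_deltas`
#'   (the FASTPAM1 TD change of each applied swap), `k`, `init`, and `call`.
#' @seealso [silhouette_width()] for cluster-quality assessment,
#'   [build_init()], [lab_init()], [fastpam1()] for the individual phases.
#' @export
#' @examples
#' D <- pairwise_dissimilarity(make_line_fixture(), "L1")
#' fit <- scpam(D, k = 2)
#' fit$medoids  # points at values 1 and 11
#' fit$td       # 4, the global optimum
scpam <- function(D, k, init = c("build", "lab"), seed = NULL,
                  max_iter = 1000L, workers = 1L) {
  init <- match.arg(init)
  dv <- as_diss_values(D)
  med0 <- if (init == "build") build_init(dv, k)
          else lab_init(dv, k, seed = seed)
  fit <- fastpam1(dv, med0, max_iter = max_iter, workers = workers)
  fit$init <- init
  fit$seed <- seed
  fit$call <- match.call()
  fit
}

#' BUILD initialization for PAM
#'
#' Deterministic greedy seeding: the first medoid is the point with the
#' smallest sum of dissimilarities to all others; each subsequent medoid is
#' the non-medoid whose addition yields the largest reduction in total
#' deviation, \eqn{\sum_j \max(d_1(j) - D(j, c), 0)} where \eqn{d_1(j)} is
#' the distance of point j to its nearest current medoid. All ties break to
#' the lowest index.
#'
#' @inheritParams scpam
#' @return Integer vector of `k` distinct medoid indices, in selection order.
#' @export
build_init <- function(D, k) {
  dv <- as_diss_values(D)
  n <- nrow(dv)
  k <- check_k(k, n)
  medoids <- integer(k)
  medoids[1] <- which.min(rowSums(dv)) # which.min takes the first (lowest) tie
  d1 <- dv[, medoids[1]]
  for (t in seq_len(k - 1L)) {
    gain <- colSums(pmax(d1 - dv, 0))
    gain[medoids[seq_len(t)]] <- -Inf
    medoids[t + 1L] <- which.max(gain)
    d1 <- pmin(d1, dv[, medoids[t + 1L]])
  }
  medoids
}

#' LAB initialization for PAM
#'
#' Randomized variant of [build_init()] (\dQuote{linear approximative
#' BUILD}): each of the k greedy choices is evaluated on a fresh uniform
#' random subsample of size `min(n, 10 + ceiling(sqrt(n)))` drawn without
#' replacement — both the candidate set (current medoids excluded) and the
#' points over which the TD reduction is summed are restricted to the
#' subsample. Fully reproducible given `seed`; if the subsample covers all n
#' points the result equals [build_init()] exactly.
#'
#' @inheritParams scpam
#' @param subsample_size override for the subsample size (mainly for
#'   testing); default `min(n, 10 + ceiling(sqrt(n)))`.
#' @return Integer vector of `k` distinct medoid indices.
#' @export
lab_init <- function(D, k, seed = NULL, subsample_size = NULL) {
  dv <- as_diss_values(D)
  n <- nrow(dv)
  k <- check_k(k, n)
  s <- if (is.null(subsample_size)) min(n, 10L + as.integer(ceiling(sqrt(n))))
       else min(n, as.integer(subsample_size))
  with_seed(seed, {
    medoids <- integer(0)
    d1 <- rep(Inf, n)
    for (t in seq_len(k)) {
      sub <- sort(sample.int(n, s))
      cand <- setdiff(sub, medoids)
      if (length(medoids) == 0L) {
        # first medoid: smallest sum of dissimilarities within the subsample
        sums <- colSums(dv[sub, cand, drop = FALSE])
        best <- cand[which.min(sums)]
      } else {
        gain <- colSums(pmax(d1[sub] - dv[sub, cand, drop = FALSE], 0))
        best <- cand[which.max(gain)]
      }
      medoids <- c(medoids, best)
      d1 <- pmin(d1, dv[, best])
    }
    medoids
  })
}

#' FASTPAM1 swap phase
#'
#' Runs the FASTPAM1 swap optimization from a given medoid set (see
#' [scpam()] for the algorithm). Exposed separately so initialization and
#' optimization can be composed and inspected; `max_iter = 0` performs the
#' assignment only.
#'
#' @inheritParams scpam
#' @param medoids integer vector of distinct starting medoid indices.
#' @return An `scpam` object (without `init`/`call` fields).
#' @export
fastpam1 <- function(D, medoids, max_iter = 1000L, workers = 1L) {
  dv <- as_diss_values(D)
  n <- nrow(dv)
  workers <- check_workers(workers)
  medoids <- as.integer(medoids)
  if (anyDuplicated(medoids) || any(medoids < 1L) || any(medoids > n))
    stop("medoids must be distinct indices in 1..n")
  if (max_iter < 0) stop("max_iter must be >= 0")
  res <- cpp_fastpam1(dv, medoids - 1L, as.integer(max_iter), workers)
  nms <- rownames(dv)
  assignment <- res$assignment + 1L
  names(assignment) <- nms
  structure(list(
    medoids = res$medoids + 1L,
    medoid_names = if (!is.null(nms)) nms[res$medoids + 1L] else NULL,
    assignment = assignment,
    td = res$td,
    n_swaps = res$n_swaps,
    iterations = res$iterations,
    converged = res$converged,
    td_trace = res$td_trace,
    applied_deltas = res$applied_deltas,
    k = length(medoids),
    n = n), class = "scpam")
}

check_k <- function(k, n) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k >= n)
    stop(sprintf("k must satisfy 1 <= k < n (got k=%s, n=%d)", k, n))
  k
}

# evaluate a block of code under a temporary RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

## ---- methods ----------------------------------------------------------------

#' @export
#' @method print scpam
print.scpam <- function(x, ...) {
  cat(sprintf("k-medoids (PAM/FASTPAM1) clustering: k = %d, n = %d\n", x$k, x$n))
  med <- if (!is.null(x$medoid_names)) x$medoid_names else x$medoids
  cat("medoids:", paste(med, collapse = ", "), "\n")
  cat(sprintf("total deviation: %g  (%d swap%s, %s)\n", x$td, x$n_swaps,
              if (x$n_swaps == 1) "" else "s",
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}

#' @export
#' @method summary scpam
summary.scpam <- function(object, ...) {
  sizes <- tabulate(object$assignment, nbins = object$k)
  structure(list(fit = object, sizes = sizes), class = "summary.scpam")
}

#' @export
#' @method print summary.scpam
print.summary.scpam <- function(x, ...) {
  print(x$fit)
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("TD trace:", paste(signif(x$fit$td_trace, 6), collapse = " -> "), "\n")
  invisible(x)
}

#' Plot a PAM clustering
#'
#' With a dissimilarity matrix supplied, draws the silhouette profile
#' (per-point widths sorted within clusters); otherwise a barplot of cluster
#' sizes.
#'
#' @param x an `scpam` fit.
#' @param D optional dissimilarity matrix used for the fit.
#' @param ... passed to [graphics::barplot()].
#' @return The fit, invisibly.
#' @export
plot.scpam <- function(x, D = NULL, ...) {
  if (!is.null(D)) {
    sil <- silhouette_width(D, x)
    ord <- order(x$assignment, -sil$s)
    graphics::barplot(rev(sil$s[ord]), horiz = TRUE, border = NA,
                      col = rev(x$assignment[ord]) + 1L,
                      xlab = "silhouette width", ...)
    graphics::abline(v = sil$overall_mean, lty = 2)
  } else {
    sizes <- tabulate(x$assignment, nbins = x$k)
    graphics::barplot(sizes, names.arg = seq_len(x$k),
                      xlab = "cluster", ylab = "size", ...)
  }
  invisible(x)
}
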