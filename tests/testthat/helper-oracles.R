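# Independent naive reference implementations used as oracles.  These are
# deliberately written as plain double loops over the definitions and share
# no code with the package internals.

naive_diss <- function(X, metric, w = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- X[i, ]
    xj <- X[j, ]
    D[i, j] <- switch(metric,
      L1 = sum(abs(xi - xj)),
      L2 = sqrt(sum((xi - xj)^2)),
      weighted_euclidean = sqrt(sum(w * (xi - xj)^2)),
      pearson = 1 - stats::cor(xi, xj),
      cosine = 1 - sum(xi * xj) / (sqrt(sum(xi^2)) * sqrt(sum(xj^2))))
  }
  D
}

# TD of a medoid set, recomputed from scratch
td_of <- function(D, medoids) {
  D <- as.matrix(D)
  sum(apply(D[, medoids, drop = FALSE], 1, min))
}

# global optimum by exhaustive search over all k-subsets
brute_force_best <- function(D, k) {
  D <- as.matrix(D)
  n <- nrow(D)
  sets <- utils::combn(n, k)
  tds <- apply(sets, 2, function(m) td_of(D, m))
  list(td = min(tds), medoids = sets[, which.min(tds)])
}

# best TD over all single swaps from a medoid set (inclusive of no swap)
best_single_swap_td <- function(D, medoids) {
  D <- as.matrix(D)
  n <- nrow(D)
  best <- td_of(D, medoids)
  for (s in seq_along(medoids)) {
    for (c in setdiff(seq_len(n), medoids)) {
      cand <- medoids
      cand[s] <- c
      best <- min(best, td_of(D, cand))
    }
  }
  best
}

naive_silhouette <- function(D, asg) {
  D <- as.matrix(D)
  n <- nrow(D)
  ks <- sort(unique(asg))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(asg == asg[i])
    if (length(own) == 1L) {
      s[i] <- 0
      next
    }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(ks, asg[i]),
                    function(kk) mean(D[i, asg == kk]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# adjusted Rand index between two partitions (closed form on the
# contingency table; independent of any clustering code)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

rand_diss <- function(n, seed, d = 2L) {
  set.seed(seed)
  X <- matrix(stats::runif(n * d, 0, 10), n, d)
  as.matrix(stats::dist(X))
}
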