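Package: scmedoids
Title: Parallel k-Medoids (PAM) Clustering for Large Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Memory-lean k-medoids (PAM) clustering aimed at large single-cell
    RNA-seq experiments. Provides a compact binary container for full, sparse
    and symmetric 2D matrices with selectable value types (including 32-bit
    floats to halve the footprint of dissimilarity matrices); parallel,
    sparse-aware computation of five pairwise dissimilarities (Manhattan,
    Euclidean, Pearson, cosine, weighted Euclidean); PAM with deterministic
    BUILD or randomized LAB initialization and the FASTPAM1 swap phase;
    silhouette widths for cluster-quality assessment; and a single-cell front
    end (count-matrix ingestion, log1p normalization, highly-variable-gene
    selection, cluster-by-condition abundance tables). Results are
    deterministic and independent of the number of worker threads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    graphics,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
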