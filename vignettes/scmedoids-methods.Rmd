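---
title: "Methods: k-medoids clustering with scmedoids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-medoids clustering with scmedoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmedoids)
```

## The model

PAM (partitioning around medoids, k-medoids) selects k data points as
medoids $M = \{m_1, \dots, m_k\}$ and assigns every point to its nearest
medoid, minimizing the total deviation

$$TD = \sum_{i=1}^{k} \sum_{x \in C_i} d(x, m_i),$$

where $d$ is any dissimilarity. Unlike k-means, PAM makes no geometric
assumptions: it never averages points, so it works directly on Pearson or
cosine dissimilarities and is robust to the heavy-tailed, non-Euclidean
structure typical of single-cell expression data. Its inputs here are always
a precomputed symmetric dissimilarity matrix, which is also its main cost:
$O(n^2)$ memory and $O(n^2 d)$ time to build.

The pipeline this package implements for single-cell data is: read a count
matrix (cells × genes after the optional transpose), normalize each count $c$
to $\log(1 + c)$, keep the most variable genes, compute a dissimilarity
matrix between cells, run PAM, and evaluate the clustering with silhouette
widths and a cluster × condition abundance table.

## Dissimilarities

Five metrics between rows $x_i, x_j \in \mathbb{R}^d$:

| metric | definition | range |
|---|---|---|
| `L1` | $\sum_f \lvert x_{if} - x_{jf}\rvert$ | $[0,\infty)$ |
| `L2` | $\sqrt{\sum_f (x_{if} - x_{jf})^2}$ | $[0,\infty)$ |
| `weighted_euclidean` | $\sqrt{\sum_f w_f (x_{if} - x_{jf})^2}$ | $[0,\infty)$ |
| `pearson` | $1 - r(x_i, x_j)$ | $[0,2]$ |
| `cosine` | $1 - \frac{x_i \cdot x_j}{\lVert x_i\rVert\,\lVert x_j\rVert}$ | $[0,2]$ for non-negative data |

Design choices that were genuinely open:

* **Pearson dissimilarity is $1 - r$**, not $(1-r)/2$: it matches the
  convention of the established R clustering ecosystem and keeps perfect
  anticorrelation at the intuitive value 2.
* **Weights for the weighted Euclidean metric are user-supplied** (one
  non-negative weight per feature). No automatic derivation is attempted.
* **Degenerate rows are hard errors.** A zero-variance row under `pearson`
  or a zero-norm row under `cosine` raises an error naming the row instead
  of emitting NaN — a NaN entry would silently corrupt every later PAM
  comparison it participates in.

### The sparse fast path

Single-cell matrices are mostly zeros. For sparse input the kernels merge the
two rows' sorted nonzero index lists, so the inner loop visits only the
*union of supports*; for `pearson`/`cosine` the cross term needs only the
*intersection*, combined with per-row aggregates ($\sum x$, $\sum x^2$,
$\lVert x \rVert$) computed once. Because skipped terms contribute exact
zeros to the same left-to-right summation order, the sparse and dense paths
agree bitwise in practice; the tests assert $10^{-12}$ relative (float64) and
$10^{-6}$ (float32) without relying on that stronger coincidence.

### float32 storage

With `dtype = "float32"`, per-entry arithmetic runs in IEEE single precision
and the result is widened to double, exactly emulating a dissimilarity
matrix stored as floats (half the memory at n×n scale). TD and all swap
bookkeeping accumulate in double regardless, which bounds drift; the
acceptance script measures the resulting TD discrepancy on 3-cluster data
(n ≈ 2000) and the suite requires it below 1%.

## PAM phases

**BUILD** (deterministic): the first medoid is the point minimizing the sum
of dissimilarities to all others; each next medoid is the candidate $c$
maximizing the TD reduction $\sum_j \max(d_1(j) - D(j, c), 0)$, with
$d_1(j)$ the distance of $j$ to its current nearest medoid.

**LAB** (randomized): the same greedy criterion evaluated on a fresh uniform
subsample (without replacement) per medoid choice, with candidates and the
reduction sum both restricted to the subsample. The subsample size is
$\min(n, 10 + \lceil\sqrt n\rceil)$, following the linear-approximative-BUILD
literature; nothing in this package depends on the constant beyond tests
asserting reproducibility and the exact degeneration to BUILD when the
subsample covers all points.

**FASTPAM1 swap phase**: for one entering candidate $c$, a single pass over
all points $j$ with cached nearest/second-nearest distances $d_1, d_2$
accumulates

$$A_i = \sum_{\mathrm{nearest}(j)=i} \bigl(\min(d_{cj}, d_2(j)) - d_1(j)\bigr),
\quad S = \sum_j \min(d_{cj} - d_1(j),\, 0),
\quad S_i = \sum_{\mathrm{nearest}(j)=i} \min(d_{cj} - d_1(j),\, 0),$$

giving the TD change of swapping medoid slot $i$ for $c$ as
$\Delta TD(i, c) = A_i + S - S_i$ — all k swaps for one candidate in $O(n)$
rather than $O(nk)$.

Open choices, and why they were made this way:

* **Best-single-swap per iteration** (not eager first-improvement): it
  reproduces the classic PAM trajectory, is independent of candidate
  visiting order, and makes the whole algorithm deterministic. The suite
  cross-checks the final TD against `cluster::pam(pamonce = 5)` on
  well-separated data.
* **Ties break to the lowest (candidate, medoid-slot) pair**, and to the
  lowest index in BUILD and in assignment. Dissimilarity ties are common in
  discrete data; a fixed order makes results exactly reproducible and
  testable.
* **A swap is applied only if $\Delta TD < 0$ strictly**, so TD strictly
  decreases and termination is guaranteed on the finite configuration
  space. `max_iter` (default 1000) is an emergency brake, far above the
  iteration counts observed in any test.
* **TD is recomputed from the refreshed cache after each swap** rather than
  accumulated, so the reported objective cannot drift; the predicted
  $\Delta TD$ of every applied swap is separately reported (`applied_deltas`)
  and checked against from-scratch differences to $10^{-9}$.

PAM is a local search. On 30 fixed random instances with $n \in [8, 12]$ and
$k \in \{2, 3\}$, the returned TD equals the exhaustive-search optimum in 26
of 30 cases (the tests pin this frequency); in the remaining cases it is a
1-swap-stable local optimum strictly above it. The suite separately verifies
that *no* returned clustering, at any tested size, admits an improving single
swap.

## Silhouette

For point $i$ in cluster $C$: $a(i)$ is the mean dissimilarity to the other
members of $C$, $b(i)$ the smallest mean dissimilarity to any other cluster,
and $s(i) = (b - a)/\max(a, b) \in [-1, 1]$. Singletons score 0 by the
standard convention. Two deliberate edges:

* **k = 1 is an error**, not an all-zero vector: $b(i)$ is undefined, and a
  silent 0 would mislead the k-selection workflow silhouettes exist for.
* The implementation is one dense product with the cluster indicator matrix;
  a naive $O(n^2)$ double-loop oracle in the tests agrees to $10^{-12}$.

## The binary container

The container exists so that a 30 GB dissimilarity matrix never has to pass
through R's double-only, copy-happy matrix semantics to be stored or
inspected. The dialect is fixed and documented in `R/matrix-store.R`:
little-endian, magic `JMTX`, a 48-byte header (kind, value type, dimensions
as unsigned 64-bit, metadata flags, payload offset), then the payload —
row-major for FULL, per-row count/indices/values for SPARSE, packed lower
triangle *including the diagonal* for SYMMETRIC (n(n+1)/2 values) — and
length-prefixed UTF-8 name/comment blocks after it. Keeping the diagonal
stored keeps the container generic (dissimilarity writers simply write
zeros); matrix indices are 32-bit unsigned, so each dimension must stay below
$2^{32}$. There are no timestamps, so identical input produces byte-identical
files — the property the determinism tests lean on.

Value types are `uint8`, `int32`, `uint32`, `int64`, `float32`, `float64`.
Two portability notes: 80-bit extended floats are not offered (not
representable portably), and `int64` values are exact only within
$\pm 2^{53}$ because R's numeric carrier is the IEEE double. Out-of-range or
non-integral values for a declared type are rejected at write time with the
offending element named. `peek_header()` reads exactly the 48-byte header —
the tests verify it succeeds on a file truncated to 48 bytes.

## Parallelism contract

`workers` partitions independent work (matrix entries; swap candidates)
statically across OpenMP threads; every reduction that could depend on order
(the best-swap argmin) runs sequentially in fixed index order. The contract
is therefore *bitwise equality of results for any worker count*, which the
tests assert for distances, PAM and silhouettes — not merely statistical
equivalence. Builds without OpenMP run the same code serially and produce
the same bytes.

## Synthetic data: what it does and does not show

The generators are pure functions of their arguments (seed included):

* `make_line_fixture()` — the six points (0, 1, 2, 10, 11, 12), small enough
  that the k = 2 optimum (medoids at values 1 and 11, TD = 4 under L1) is
  verified by exhaustive search over all 15 medoid pairs.
* `make_blobs()` — isotropic Gaussian clusters with a recorded
  separation/σ ratio; used for parameter recovery (at ratio ≥ 100 the
  planted partition must be recovered exactly, ARI = 1) and for the
  float32/float64 comparison at n ≈ 2000 — sizes chosen so the full suite
  runs in seconds while still exercising the cached-swap code path over
  thousands of points.
* `make_sparse_counts()` — uniform nonzero positions with Poisson(rate) + 1
  values, so the declared density is exact by construction.

These fixtures emulate the *structural* properties the algorithms depend on
(sparsity pattern, separated clusters, ties) but not the statistics of real
scRNA-seq: no library-size variation, no gene-wise overdispersion, no
dropout correlation, no batch structure. Passing tests therefore certify the
algorithms and their numerics, not biological performance on real tissue;
on real data the choice of metric, gene count and k remains the analyst's,
guided by silhouette and interpretation.

## Front-end choices

* **Normalization is log1p only** — $\log(c+1)$, zeros to zeros, sparsity
  preserved. Per-cell depth normalization is deliberately not bundled; apply
  it upstream if your workflow calls for it.
* **HVG selection ranks genes by sample variance of the (normalized) values**
  as given, ties to the lower column index, original column order preserved.
  Variance of log1p values is the simplest defensible reading of "most
  highly variable genes" on log-normalized data; no mean–variance trend
  fitting is attempted.
* **The abundance matrix** counts cells per (cluster, condition) with
  condition columns in first-appearance order, plus row-normalized
  proportions; its row sums are the cluster sizes and its total is n, both
  asserted by tests.

## Known limitations

* Only the swap variant FASTPAM1 with best-swap policy is implemented — no
  eager FasterPAM, no CLARA-style subsampled PAM for data that cannot hold
  an n×n matrix.
* The dissimilarity matrix is held dense in memory while clustering (the
  packed lower triangle exists on disk only), so practical n is bounded by
  RAM: n = 50,000 in float32 is ~10 GB on disk but 20 GB as an in-memory
  double matrix.
* No automatic choice of k; compute silhouettes across a k range instead.
* The container dialect is this package's own; no compatibility with any
  other binary matrix format is claimed.
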