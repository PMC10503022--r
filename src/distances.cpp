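// Pairwise dissimilarity kernels.
//
// Every matrix entry (i,j) is computed independently from the two rows, so
// results are bitwise identical for any number of OpenMP threads (static
// schedule, no shared accumulators).  When `use_float32` is set, all
// per-entry arithmetic is carried out in IEEE single precision and the
// result widened to double, emulating a float-typed dissimilarity matrix.
//
// The sparse kernels only visit the union of the two rows' nonzero index
// sets (plus O(1) per-row aggregates for the correlation / cosine cross
// terms); zero-zero feature pairs are never touched.

#include <Rcpp.h>
#include <cmath>
#ifdef _OPENMP
#include <omp.h>
#endif

using namespace Rcpp;

enum Metric { M_L1 = 0, M_L2 = 1, M_PEARSON = 2, M_COSINE = 3, M_WEUC = 4 };

template <typename T>
static inline double dense_pair(const double* xi, const double* xj, int d,
                                int metric, const double* w,
                                T sx_i, T sx_j, T sxx_i, T sxx_j) {
  T acc = 0;
  switch (metric) {
  case M_L1:
    for (int f = 0; f < d; ++f) acc += std::abs((T)xi[f] - (T)xj[f]);
    return (double)acc;
  case M_L2:
    for (int f = 0; f < d; ++f) {
      T dd = (T)xi[f] - (T)xj[f];
      acc += dd * dd;
    }
    return (double)std::sqrt(acc);
  case M_WEUC:
    for (int f = 0; f < d; ++f) {
      T dd = (T)xi[f] - (T)xj[f];
      acc += (T)w[f] * dd * dd;
    }
    return (double)std::sqrt(acc);
  case M_COSINE: {
    for (int f = 0; f < d; ++f) acc += (T)xi[f] * (T)xj[f];
    T denom = std::sqrt(sxx_i) * std::sqrt(sxx_j);
    return (double)((T)1 - acc / denom);
  }
  case M_PEARSON: {
    for (int f = 0; f < d; ++f) acc += (T)xi[f] * (T)xj[f];
    T n = (T)d;
    T num = n * acc - sx_i * sx_j;
    T den = std::sqrt(n * sxx_i - sx_i * sx_i) * std::sqrt(n * sxx_j - sx_j * sx_j);
    return (double)((T)1 - num / den);
  }
  }
  return NA_REAL; // unreachable
}

template <typename T>
static void dense_all(const NumericMatrix& X, int metric, const double* w,
                      NumericMatrix& out, int threads) {
  const int n = X.nrow(), d = X.ncol();
  // row-major copy so each row is contiguous
  std::vector<double> R((size_t)n * d);
  std::vector<T> sx(n, 0), sxx(n, 0);
  for (int i = 0; i < n; ++i) {
    for (int f = 0; f < d; ++f) {
      double v = X(i, f);
      R[(size_t)i * d + f] = v;
      sx[i] += (T)v;
      sxx[i] += (T)v * (T)v;
    }
  }
#ifdef _OPENMP
#pragma omp parallel for num_threads(threads) schedule(static)
#endif
  for (int i = 0; i < n; ++i) {
    const double* xi = &R[(size_t)i * d];
    for (int j = 0; j < i; ++j) {
      const double* xj = &R[(size_t)j * d];
      double v = dense_pair<T>(xi, xj, d, metric, w, sx[i], sx[j], sxx[i], sxx[j]);
      out(i, j) = v;
      out(j, i) = v;
    }
    out(i, i) = 0.0;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_pairwise_dense(NumericMatrix X, int metric, NumericVector w,
                                 bool use_float32, int threads) {
  const int n = X.nrow();
  NumericMatrix out(n, n);
  const double* wp = (metric == M_WEUC) ? REAL(w) : (const double*)nullptr;
  if (use_float32)
    dense_all<float>(X, metric, wp, out, threads);
  else
    dense_all<double>(X, metric, wp, out, threads);
  return out;
}

// Sparse rows in CSR form.  ptr has n+1 entries; idx ascending within a row.
template <typename T>
static inline double sparse_pair(const int* ia, const double* xa, int na,
                                 const int* ib, const double* xb, int nb,
                                 int d, int metric, const double* w,
                                 T sx_i, T sx_j, T sxx_i, T sxx_j) {
  T acc = 0;
  if (metric == M_L1 || metric == M_L2 || metric == M_WEUC) {
    int p = 0, q = 0;
    while (p < na || q < nb) {
      T dd;
      int f;
      if (q >= nb || (p < na && ia[p] < ib[q])) {
        f = ia[p]; dd = (T)xa[p]; ++p;
      } else if (p >= na || ib[q] < ia[p]) {
        f = ib[q]; dd = -(T)xb[q]; ++q;
      } else {
        f = ia[p]; dd = (T)xa[p] - (T)xb[q]; ++p; ++q;
      }
      if (metric == M_L1) acc += std::abs(dd);
      else if (metric == M_L2) acc += dd * dd;
      else acc += (T)w[f] * dd * dd;
    }
    return metric == M_L1 ? (double)acc : (double)std::sqrt(acc);
  }
  // cross term over the support intersection only
  int p = 0, q = 0;
  while (p < na && q < nb) {
    if (ia[p] < ib[q]) ++p;
    else if (ib[q] < ia[p]) ++q;
    else { acc += (T)xa[p] * (T)xb[q]; ++p; ++q; }
  }
  if (metric == M_COSINE) {
    T denom = std::sqrt(sxx_i) * std::sqrt(sxx_j);
    return (double)((T)1 - acc / denom);
  }
  T n = (T)d;
  T num = n * acc - sx_i * sx_j;
  T den = std::sqrt(n * sxx_i - sx_i * sx_i) * std::sqrt(n * sxx_j - sx_j * sx_j);
  return (double)((T)1 - num / den);
}

template <typename T>
static void sparse_all(const IntegerVector& ptr, const IntegerVector& idx,
                       const NumericVector& val, int n, int d, int metric,
                       const double* w, NumericMatrix& out, int threads) {
  std::vector<T> sx(n, 0), sxx(n, 0);
  for (int i = 0; i < n; ++i)
    for (int p = ptr[i]; p < ptr[i + 1]; ++p) {
      T v = (T)val[p];
      sx[i] += v;
      sxx[i] += v * v;
    }
  const int* ip = INTEGER(idx);
  const double* vp = REAL(val);
#ifdef _OPENMP
#pragma omp parallel for num_threads(threads) schedule(static)
#endif
  for (int i = 0; i < n; ++i) {
    const int* ia = ip + ptr[i];
    const double* xa = vp + ptr[i];
    int na = ptr[i + 1] - ptr[i];
    for (int j = 0; j < i; ++j) {
      double v = sparse_pair<T>(ia, xa, na, ip + ptr[j], vp + ptr[j],
                                ptr[j + 1] - ptr[j], d, metric, w,
                                sx[i], sx[j], sxx[i], sxx[j]);
      out(i, j) = v;
      out(j, i) = v;
    }
    out(i, i) = 0.0;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_pairwise_sparse(IntegerVector ptr, IntegerVector idx,
                                  NumericVector val, int n, int d, int metric,
                                  NumericVector w, bool use_float32,
                                  int threads) {
  NumericMatrix out(n, n);
  const double* wp = (metric == M_WEUC) ? REAL(w) : (const double*)nullptr;
  if (use_float32)
    sparse_all<float>(ptr, idx, val, n, d, metric, wp, out, threads);
  else
    sparse_all<double>(ptr, idx, val, n, d, metric, wp, out, threads);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_float32_round(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = (double)(float)x[i];
  return out;
}
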