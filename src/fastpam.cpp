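// FASTPAM1 swap phase.
//
// For one candidate c entering the medoid set, a single pass over all points
// j accumulates, using the cached nearest (d1) and second-nearest (d2)
// medoid distances,
//   A_i = sum_{nearest(j)=i} ( min(D(c,j), d2(j)) - d1(j) )
//   S   = sum_j               min(D(c,j) - d1(j), 0)
//   S_i = sum_{nearest(j)=i}  min(D(c,j) - d1(j), 0)
// so the TD change of swapping medoid slot i for c is
//   dTD(i, c) = A_i + S - S_i .
// Per iteration the single best strictly negative swap is applied, ties
// broken by lowest (candidate index, medoid slot).  Candidates are
// independent, so the candidate loop parallelizes with bitwise-identical
// results for any thread count; the argmin reduction is sequential in
// candidate order.  All accumulation is in double regardless of how the
// dissimilarity matrix was stored.

#include <Rcpp.h>
#include <cfloat>
#ifdef _OPENMP
#include <omp.h>
#endif

using namespace Rcpp;

// nearest/second-nearest cache; nearest slot ties break to the lowest slot
static void update_cache(const NumericMatrix& D, const std::vector<int>& med,
                         std::vector<int>& nearest, std::vector<double>& d1,
                         std::vector<double>& d2) {
  const int n = D.nrow(), k = (int)med.size();
  for (int j = 0; j < n; ++j) {
    double b1 = DBL_MAX, b2 = DBL_MAX;
    int s1 = -1;
    for (int i = 0; i < k; ++i) {
      double d = D(med[i], j);
      if (d < b1) {
        b2 = b1;
        b1 = d;
        s1 = i;
      } else if (d < b2) {
        b2 = d;
      }
    }
    nearest[j] = s1;
    d1[j] = b1;
    d2[j] = b2;
  }
}

// [[Rcpp::export]]
List cpp_fastpam1(NumericMatrix D, IntegerVector medoids0, int max_iter,
                  int threads) {
  const int n = D.nrow();
  const int k = medoids0.size();
  std::vector<int> med(medoids0.begin(), medoids0.end()); // 0-based
  std::vector<int> nearest(n);
  std::vector<double> d1(n), d2(n);
  std::vector<char> is_med(n, 0);
  for (int i = 0; i < k; ++i) is_med[med[i]] = 1;
  update_cache(D, med, nearest, d1, d2);

  std::vector<double> applied_deltas, td_trace;
  double td = 0.0;
  for (int j = 0; j < n; ++j) td += d1[j];
  td_trace.push_back(td);

  bool converged = false;
  int n_swaps = 0, iter = 0;
  std::vector<double> best_delta(n);
  std::vector<int> best_slot(n);
  while (iter < max_iter) {
    ++iter;
#ifdef _OPENMP
#pragma omp parallel for num_threads(threads) schedule(static)
#endif
    for (int c = 0; c < n; ++c) {
      if (is_med[c]) {
        best_delta[c] = DBL_MAX;
        continue;
      }
      std::vector<double> A(k, 0.0), S1(k, 0.0);
      double S = 0.0;
      for (int j = 0; j < n; ++j) {
        double d = D(c, j);
        int i = nearest[j];
        double diff = d - d1[j];
        if (diff < 0) {
          S += diff;
          S1[i] += diff;
        }
        double rep = d < d2[j] ? d : d2[j]; // min(D(c,j), d2(j))
        A[i] += rep - d1[j];
      }
      double bd = DBL_MAX;
      int bs = -1;
      for (int i = 0; i < k; ++i) {
        double delta = A[i] + S - S1[i];
        if (delta < bd) {
          bd = delta;
          bs = i;
        }
      }
      best_delta[c] = bd;
      best_slot[c] = bs;
    }
    // sequential reduction in candidate order (deterministic tie-break)
    double bd = DBL_MAX;
    int bc = -1;
    for (int c = 0; c < n; ++c) {
      if (!is_med[c] && best_delta[c] < bd) {
        bd = best_delta[c];
        bc = c;
      }
    }
    if (bc < 0 || bd >= 0) {
      converged = true;
      break;
    }
    int slot = best_slot[bc];
    is_med[med[slot]] = 0;
    med[slot] = bc;
    is_med[bc] = 1;
    ++n_swaps;
    applied_deltas.push_back(bd);
    update_cache(D, med, nearest, d1, d2);
    td = 0.0;
    for (int j = 0; j < n; ++j) td += d1[j];
    td_trace.push_back(td);
  }

  // final assignment: lowest slot wins ties (cache already does this)
  IntegerVector assign(n);
  for (int j = 0; j < n; ++j) assign[j] = nearest[j];
  return List::create(_["medoids"] = IntegerVector(med.begin(), med.end()),
                      _["assignment"] = assign, _["td"] = td,
                      _["n_swaps"] = n_swaps, _["iterations"] = iter,
                      _["converged"] = converged,
                      _["applied_deltas"] = NumericVector(applied_deltas.begin(), applied_deltas.end()),
                      _["td_trace"] = NumericVector(td_trace.begin(), td_trace.end()));
}
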