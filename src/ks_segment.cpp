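#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Two-sample Kolmogorov-Smirnov distance between x[0..t) and x[t..n) for every
// admissible cut t, evaluated on the pooled empirical CDFs.  The scan keeps the
// pooled sort order fixed and flips one element from the right sample to the
// left sample as t advances, so each cut costs O(n) and a full scan O(n^2).
//
// Ties: |F_L - F_R| is only a realizable CDF difference at the last element of
// a run of equal values, so other positions are masked out of the maximum.

namespace {

struct ScanState {
  int n;
  bool has_ties;
  std::vector<int> pos_of_index;   // sorted position of each original index
  std::vector<unsigned char> is_left;
  std::vector<unsigned char> eval_ok; // last element of a tie run?
};

void init_scan(const double* x, int n, ScanState& st) {
  st.n = n;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return x[a] < x[b]; });
  st.pos_of_index.assign(n, 0);
  for (int k = 0; k < n; ++k) st.pos_of_index[ord[k]] = k;
  st.is_left.assign(n, 0);
  st.eval_ok.assign(n, 1);
  st.has_ties = false;
  for (int k = 0; k + 1 < n; ++k)
    if (x[ord[k]] == x[ord[k + 1]]) { st.eval_ok[k] = 0; st.has_ties = true; }
}

// D for the split at t given current is_left flags (exactly t left flags set).
double ks_at_cut(const ScanState& st, int t) {
  const int n = st.n;
  const int64_t nn = n, tt = t;
  int64_t cum = 0, best = 0;
  if (!st.has_ties) {
    // fast path: every pooled point is a valid CDF evaluation point
    const unsigned char* L = st.is_left.data();
    for (int k = 0; k < n; ++k) {
      cum += L[k];
      int64_t v = cum * nn - (int64_t)(k + 1) * tt;
      v = v < 0 ? -v : v;
      best = v > best ? v : best;
    }
  } else {
    for (int k = 0; k < n; ++k) {
      cum += st.is_left[k];
      if (!st.eval_ok[k]) continue;
      int64_t v = cum * nn - (int64_t)(k + 1) * tt;
      if (v < 0) v = -v;
      if (v > best) best = v;
    }
  }
  return (double)best / ((double)t * (double)(n - t));
}

} // namespace

// Maximal KS distance over all cuts t in [l0, n - l0] of x (0-based; cut t
// splits into x[0..t) and x[t..n)).  Returns cut (1-based position convention
// handled in R), D at the cut, and the smallest-t tie-break.
// [[Rcpp::export]]
List max_ks_cut_cpp(NumericVector x, int l0) {
  const int n = x.size();
  if (l0 < 1) stop("l0 must be >= 1");
  if (n < 2 * l0) stop("window shorter than 2*l0");
  ScanState st;
  init_scan(REAL(x), n, st);
  // flags for t = l0: indices 0..l0-1 are left
  for (int i = 0; i < l0; ++i) st.is_left[st.pos_of_index[i]] = 1;
  int best_t = l0;
  double best_d = ks_at_cut(st, l0);
  for (int t = l0 + 1; t <= n - l0; ++t) {
    st.is_left[st.pos_of_index[t - 1]] = 1;
    double d = ks_at_cut(st, t);
    if (d > best_d + 1e-15) { // strict improvement => smallest t on ties
      best_d = d;
      best_t = t;
    }
  }
  return List::create(_["cut"] = best_t, _["d_max"] = best_d);
}

// Full profile of D over every admissible cut (for diagnostics and tests).
// [[Rcpp::export]]
NumericVector ks_cut_profile_cpp(NumericVector x, int l0) {
  const int n = x.size();
  if (n < 2 * l0) stop("window shorter than 2*l0");
  ScanState st;
  init_scan(REAL(x), n, st);
  for (int i = 0; i < l0; ++i) st.is_left[st.pos_of_index[i]] = 1;
  const int m = n - 2 * l0 + 1;
  NumericVector out(m);
  out[0] = ks_at_cut(st, l0);
  for (int t = l0 + 1; t <= n - l0; ++t) {
    st.is_left[st.pos_of_index[t - 1]] = 1;
    out[t - l0] = ks_at_cut(st, t);
  }
  return out;
}

// Two-sample KS distance between a and b (pooled-CDF supremum).
// [[Rcpp::export]]
double ks_distance_cpp(NumericVector a, NumericVector b) {
  const int na = a.size(), nb = b.size(), n = na + nb;
  if (na == 0 || nb == 0) stop("samples must be non-empty");
  std::vector<double> x(n);
  std::vector<unsigned char> from_a(n);
  for (int i = 0; i < na; ++i) { x[i] = a[i]; from_a[i] = 1; }
  for (int i = 0; i < nb; ++i) { x[na + i] = b[i]; from_a[na + i] = 0; }
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int p, int q) { return x[p] < x[q]; });
  int64_t cum_a = 0, best = 0;
  const int64_t NA64 = na, NB64 = nb;
  for (int k = 0; k < n; ++k) {
    cum_a += from_a[ord[k]];
    if (k + 1 < n && x[ord[k]] == x[ord[k + 1]]) continue;
    // |cum_a/na - cum_b/nb| = |cum_a*nb - cum_b*na| / (na*nb)
    int64_t cum_b = (int64_t)(k + 1) - cum_a;
    int64_t v = cum_a * NB64 - cum_b * NA64;
    if (v < 0) v = -v;
    if (v > best) best = v;
  }
  return (double)best / ((double)na * (double)nb);
}

// Null distribution of D_max: n_null i.i.d. standard Gaussian series of
// length n, scanned with the same l0 restriction.  Uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector null_dmax_cpp(int n, int l0, int n_null) {
  if (n < 2 * l0) stop("n shorter than 2*l0");
  NumericVector out(n_null);
  std::vector<double> x(n);
  for (int r = 0; r < n_null; ++r) {
    for (int i = 0; i < n; ++i) x[i] = R::norm_rand();
    ScanState st;
    init_scan(x.data(), n, st);
    for (int i = 0; i < l0; ++i) st.is_left[st.pos_of_index[i]] = 1;
    double best_d = ks_at_cut(st, l0);
    for (int t = l0 + 1; t <= n - l0; ++t) {
      st.is_left[st.pos_of_index[t - 1]] = 1;
      double d = ks_at_cut(st, t);
      if (d > best_d) best_d = d;
    }
    out[r] = best_d;
    Rcpp::checkUserInterrupt();
  }
  return out;
}
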