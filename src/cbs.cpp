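#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Max over circular arcs (i, j] of the CBS two-sample statistic
//   Z(i,j) = |mean_in - mean_out| / sqrt(1/k + 1/(n-k))
// (the common scale factor 1/s is applied by the caller; it does not change
// the argmax and is invariant under permutation). Both the arc and its
// complement must contain at least min_width points. Ties keep the first
// (i, j) in scan order: i ascending, then j ascending — the brute-force
// oracle in the test suite scans in the same order.
static double scan_max(const std::vector<double> &S, int n, int min_width,
                       int *bi, int *bj) {
  const double total = S[n];
  double best = -1.0;
  *bi = 0;
  *bj = 0;
  for (int i = 0; i + min_width <= n; ++i) {
    int jmax = i + (n - min_width); // complement >= min_width
    if (jmax > n) jmax = n;
    for (int j = i + min_width; j <= jmax; ++j) {
      const int k = j - i;
      if (k == n) continue; // whole interval: no complement
      const double sum_in = S[j] - S[i];
      const double mean_in = sum_in / k;
      const double mean_out = (total - sum_in) / (n - k);
      const double z =
          std::fabs(mean_in - mean_out) / std::sqrt(1.0 / k + 1.0 / (n - k));
      if (z > best) {
        best = z;
        *bi = i;
        *bj = j;
      }
    }
  }
  return best;
}

static void partial_sums(const std::vector<double> &x, std::vector<double> &S) {
  const int n = (int)x.size();
  S[0] = 0.0;
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];
}

static double sample_sd(const NumericVector &x) {
  const int n = x.size();
  if (n < 2) return 0.0;
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += x[i];
  m /= n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (x[i] - m) * (x[i] - m);
  return std::sqrt(ss / (n - 1));
}

// [[Rcpp::export]]
List cbs_scan_cpp(NumericVector x, int min_width) {
  const int n = x.size();
  const double s = sample_sd(x);
  if (n < 2 * min_width || s <= 0.0)
    return List::create(_["i"] = 0, _["j"] = 0, _["stat"] = 0.0);
  std::vector<double> xv(x.begin(), x.end()), S(n + 1);
  partial_sums(xv, S);
  int bi, bj;
  const double raw = scan_max(S, n, min_width, &bi, &bj);
  return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = raw / s);
}

// Permutation test for the best arc. Permutations use R's RNG (so set.seed()
// in R controls them). Early stop: once the exceedance count guarantees
// p > alpha the remaining permutations cannot change the accept/reject
// decision and are skipped.
// [[Rcpp::export]]
List cbs_split_test_cpp(NumericVector x, int min_width, int n_perm,
                        double alpha) {
  const int n = x.size();
  const double s = sample_sd(x);
  if (n < 2 * min_width || s <= 0.0)
    return List::create(_["i"] = 0, _["j"] = 0, _["stat"] = 0.0,
                        _["p"] = 1.0, _["n_perm_done"] = 0);
  std::vector<double> xv(x.begin(), x.end()), S(n + 1);
  partial_sums(xv, S);
  int bi, bj;
  const double obs = scan_max(S, n, min_width, &bi, &bj);

  RNGScope scope;
  // count >= stop_count implies (count+1)/(n_perm+1) > alpha whatever follows
  const int stop_count = (int)std::ceil(alpha * (n_perm + 1.0));
  int count = 0, done = 0;
  int ti, tj;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle in place
    for (int a = n - 1; a > 0; --a) {
      int b = (int)(unif_rand() * (a + 1));
      if (b > a) b = a;
      std::swap(xv[a], xv[b]);
    }
    partial_sums(xv, S);
    const double pm = scan_max(S, n, min_width, &ti, &tj);
    if (pm >= obs - 1e-12) ++count;
    ++done;
    if (count >= stop_count) break;
  }
  const double pval = (count + 1.0) / (done + 1.0);
  return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = obs / s,
                      _["p"] = pval, _["n_perm_done"] = done);
}
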