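#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation core.  For a vector x[0..n-1] the candidate
// changes are arcs (i, j], 0 <= i < j <= n, excluding the full vector; the
// statistic is the two-sample t-like contrast of the arc mean against the
// complement mean, scaled by the overall standard deviation:
//   T(i,j) = |mean_arc - mean_comp| / (s * sqrt(1/k + 1/(n-k))).
// Both the arc and its complement must span at least min_width markers.

static double max_arc_stat(const std::vector<double>& S, int n, int min_width,
                           double s, int* bi, int* bj) {
  double best = -1.0;
  const double total = S[n];
  for (int i = 0; i + min_width <= n; ++i) {
    int jmax = n;
    for (int j = i + min_width; j <= jmax; ++j) {
      int k = j - i;
      if (k >= n) continue;                // whole vector is not a split
      int m = n - k;
      if (m < min_width) continue;
      double sum_arc = S[j] - S[i];
      double diff = sum_arc / k - (total - sum_arc) / m;
      double t = std::fabs(diff) / (s * std::sqrt(1.0 / k + 1.0 / m));
      if (t > best) { best = t; *bi = i; *bj = j; }
    }
  }
  return best;
}

static double overall_sd(const NumericVector& x) {
  int n = x.size();
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (x[i] - mean) * (x[i] - mean);
  return std::sqrt(ss / n);
}

// [[Rcpp::export(name = ".cbs_max_arc")]]
List cbs_max_arc_cpp(NumericVector x, int min_width) {
  int n = x.size();
  if (n < 2 * min_width) {
    return List::create(_["i"] = NA_INTEGER, _["j"] = NA_INTEGER,
                        _["stat"] = 0.0);
  }
  double s = overall_sd(x);
  if (s <= 0.0) {
    return List::create(_["i"] = NA_INTEGER, _["j"] = NA_INTEGER,
                        _["stat"] = 0.0);
  }
  std::vector<double> S(n + 1, 0.0);
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];
  int bi = -1, bj = -1;
  double best = max_arc_stat(S, n, min_width, s, &bi, &bj);
  return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = best);
}

// Permutation p-value for the observed max arc statistic.  Uses R's RNG
// (seed it from R for reproducibility).  Early exit once the exceedance
// count is large enough that p > alpha is certain (count > early_limit).
// [[Rcpp::export(name = ".cbs_perm_count")]]
List cbs_perm_count_cpp(NumericVector x, double obs, int n_perm,
                        int min_width, int early_limit) {
  int n = x.size();
  std::vector<double> perm(x.begin(), x.end());
  double s = overall_sd(x);
  int count = 0, done = 0;
  std::vector<double> S(n + 1, 0.0);
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle with R's uniform RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    for (int i = 0; i < n; ++i) S[i + 1] = S[i] + perm[i];
    int bi, bj;
    double mx = max_arc_stat(S, n, min_width, s, &bi, &bj);
    ++done;
    if (mx >= obs) {
      ++count;
      if (count > early_limit) break;
    }
  }
  return List::create(_["count"] = count, _["n_done"] = done);
}
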