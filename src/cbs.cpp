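// Circular binary segmentation: max arc statistic and permutation test.
//
// For a series x[0..n-1] viewed as a circle, a candidate change is a pair of
// boundaries (i, j), 0 <= i < j <= n, splitting the data into the arc
// x[i..j-1] and its complement. The statistic is the two-sample mean
// contrast
//   T(i,j) = |mean_in - mean_out| / sqrt(1/k + 1/(n-k))
// (the common scale factor is constant under permutation and therefore
// omitted), maximized over all pairs with both sides >= min_width.
// Significance is assessed by permuting the series: p = (# permutation
// maxima >= observed) / n_perm, with Besag–Clifford early stopping once the
// exceedance count already forces p >= alpha.

#include <Rcpp.h>
#include <random>
using namespace Rcpp;

namespace {

struct MaxStat {
  double stat;
  int i, j;  // boundaries: arc is (i, j] in 1-based series terms
};

// Max over all (i,j): i < j, arc length k = j - i, min_width <= k <= n - min_width.
// Ties broken toward the smallest i, then smallest j (leftmost pair).
MaxStat max_arc_stat(const std::vector<double>& x, int min_width) {
  const int n = (int)x.size();
  MaxStat best{-1.0, -1, -1};
  if (n < 2 * min_width) return best;
  std::vector<double> cs(n + 1, 0.0);
  for (int t = 0; t < n; ++t) cs[t + 1] = cs[t] + x[t];
  const double total = cs[n];
  for (int i = 0; i <= n - min_width; ++i) {
    const int jmax = std::min(n, i + (n - min_width));
    for (int j = i + min_width; j <= jmax; ++j) {
      const int k = j - i;
      const double sin_ = cs[j] - cs[i];
      const double din = sin_ / k;
      const double dout = (total - sin_) / (n - k);
      const double t2 = (din - dout) * (din - dout) /
                        (1.0 / k + 1.0 / (n - k));
      if (t2 > best.stat + 1e-12) {
        best.stat = t2;
        best.i = i;
        best.j = j;
      }
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export(name = ".cbs_max_stat")]]
List cbs_max_stat(NumericVector x, int min_width) {
  std::vector<double> v(x.begin(), x.end());
  MaxStat m = max_arc_stat(v, min_width);
  return List::create(_["stat"] = m.stat > 0 ? std::sqrt(m.stat) : 0.0,
                      _["i"] = m.i, _["j"] = m.j);
}

// Permutation p-value of the observed max arc statistic.
// Returns exceedance count and the number of permutations actually run;
// stops early once count reaches ceil(alpha * n_perm) (the split can no
// longer be significant).
// [[Rcpp::export(name = ".cbs_perm_pvalue")]]
List cbs_perm_pvalue(NumericVector x, double obs_stat, int min_width,
                     int n_perm, double alpha, int seed) {
  std::vector<double> v(x.begin(), x.end());
  const double obs2 = obs_stat * obs_stat;
  // reject as soon as (count + 1) / (n_perm + 1) >= alpha is guaranteed
  int stop_at = (int)std::ceil(alpha * (n_perm + 1) - 1.0);
  if (stop_at < 1) stop_at = 1;
  std::mt19937 rng((unsigned)seed);
  int count = 0, done = 0;
  for (int p = 0; p < n_perm; ++p) {
    std::shuffle(v.begin(), v.end(), rng);
    MaxStat m = max_arc_stat(v, min_width);
    ++done;
    if (m.stat >= obs2 - 1e-12) ++count;
    if (count >= stop_at) break;
  }
  return List::create(_["count"] = count, _["n_done"] = done);
}

// Two-sample permutation test on |mean(a) - mean(b)| for the pruning pass
// (used when segments are too small or too flat for a t-test).
// [[Rcpp::export(name = ".perm_mean_diff_pvalue")]]
double perm_mean_diff_pvalue(NumericVector a, NumericVector b, int n_perm,
                             int seed) {
  const int na = a.size(), nb = b.size(), n = na + nb;
  std::vector<double> v(n);
  for (int t = 0; t < na; ++t) v[t] = a[t];
  for (int t = 0; t < nb; ++t) v[na + t] = b[t];
  double ma = 0, mb = 0;
  for (int t = 0; t < na; ++t) ma += a[t];
  for (int t = 0; t < nb; ++t) mb += b[t];
  const double obs = std::fabs(ma / na - mb / nb);
  std::mt19937 rng((unsigned)seed);
  int count = 0;
  for (int p = 0; p < n_perm; ++p) {
    std::shuffle(v.begin(), v.end(), rng);
    double sa = 0;
    for (int t = 0; t < na; ++t) sa += v[t];
    const double sb = (ma + mb) - sa;
    if (std::fabs(sa / na - sb / nb) >= obs - 1e-12) ++count;
  }
  return (double)(count + 1) / (n_perm + 1);
}
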