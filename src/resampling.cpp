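#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

static double group_stat(std::vector<double>& g, bool use_median) {
  const size_t n = g.size();
  if (!use_median) {
    double s = 0.0;
    for (double v : g) s += v;
    return s / n;
  }
  std::sort(g.begin(), g.end());
  if (n % 2 == 1) return g[n / 2];
  return 0.5 * (g[n / 2 - 1] + g[n / 2]);
}

// Null distribution of |stat(A*) - stat(B*)| under random relabelling of the
// pooled observations. Uses R's RNG (deterministic under set.seed).
// [[Rcpp::export(name = ".perm_null")]]
NumericVector perm_null(NumericVector values, int n_a, int n_iter,
                        bool use_median) {
  const int n = values.size();
  std::vector<double> pool(values.begin(), values.end());
  std::vector<double> work(n);
  std::vector<double> ga(n_a), gb(n - n_a);
  NumericVector out(n_iter);
  for (int it = 0; it < n_iter; ++it) {
    std::copy(pool.begin(), pool.end(), work.begin());
    // partial Fisher-Yates: first n_a slots become group A
    for (int i = 0; i < n_a; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(work[i], work[j]);
    }
    ga.assign(work.begin(), work.begin() + n_a);
    gb.assign(work.begin() + n_a, work.end());
    out[it] = std::fabs(group_stat(ga, use_median) - group_stat(gb, use_median));
  }
  return out;
}
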