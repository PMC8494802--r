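#include <Rcpp.h>
using namespace Rcpp;

// Max circular binary segmentation statistic: over all arcs (i, j] of the
// (circularized) bin vector with min_width <= j - i <= n - min_width,
// the absolute standardized difference between the arc mean and the mean
// of its complement. Ties resolved toward the leftmost (i, then j).
static double max_stat(const std::vector<double> &S, int n, int min_width,
                       int *bi, int *bj) {
  double total = S[n];
  double best = -1.0;
  int besti = -1, bestj = -1;
  for (int i = 0; i <= n - min_width; i++) {
    int jmax = std::min(n, i + (n - min_width));
    for (int j = i + min_width; j <= jmax; j++) {
      int k = j - i;
      double A = S[j] - S[i];
      double z = std::fabs(A / k - (total - A) / (n - k)) /
                 std::sqrt(1.0 / k + 1.0 / (n - k));
      if (z > best + 1e-12) { best = z; besti = i; bestj = j; }
    }
  }
  if (bi) *bi = besti;
  if (bj) *bj = bestj;
  return best;
}

// [[Rcpp::export]]
List cbs_scan_cpp(NumericVector x, int min_width) {
  int n = x.size();
  std::vector<double> S(n + 1, 0.0);
  for (int t = 0; t < n; t++) S[t + 1] = S[t] + x[t];
  int bi = -1, bj = -1;
  double st = max_stat(S, n, min_width, &bi, &bj);
  return List::create(_["stat"] = st, _["i"] = bi, _["j"] = bj);
}

// Permutation p-value for the max arc statistic, with early termination
// once the exceedance count guarantees p > alpha.
// [[Rcpp::export]]
List cbs_perm_cpp(NumericVector x, int min_width, int nperm, double alpha) {
  int n = x.size();
  std::vector<double> S(n + 1, 0.0);
  for (int t = 0; t < n; t++) S[t + 1] = S[t] + x[t];
  int bi = -1, bj = -1;
  double obs = max_stat(S, n, min_width, &bi, &bj);
  std::vector<double> xp(x.begin(), x.end());
  int exceed = 0, done = 0;
  int stop_count = (int)std::ceil(alpha * nperm);
  for (int p = 0; p < nperm; p++) {
    for (int t = n - 1; t > 0; t--) {
      int u = (int)(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(xp[t], xp[u]);
    }
    S[0] = 0.0;
    for (int t = 0; t < n; t++) S[t + 1] = S[t] + xp[t];
    double st = max_stat(S, n, min_width, NULL, NULL);
    if (st >= obs - 1e-12) exceed++;
    done++;
    if (exceed > stop_count) break;
  }
  double pval = (1.0 + exceed) / (1.0 + done);
  return List::create(_["stat"] = obs, _["i"] = bi, _["j"] = bj,
                      _["p"] = pval, _["nperm_used"] = done);
}
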