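// Circular binary segmentation core: exhaustive two-breakpoint segment
// search and its within-segment permutation test.  The statistic for a
// candidate segment (i, j] against the rest of the node is
//   |mean(mid) - mean(rest)| * sqrt(m * (n - m) / n),
// computed as |D*n - m*T| / sqrt(n * m * (n - m)) with D the segment sum
// and T the node total; the pooled SD is constant under permutation and is
// dropped.  Edge-anchored segments (i == 0 or j == n) reduce to a single
// split point.  Ties resolve to the leftmost (smallest i, then j).
// Permutations draw from R's RNG, so results are reproducible from
// set.seed(); the loop stops early once significance at `alpha` is no
// longer attainable.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// best admissible segment; pieces must be empty or at least min_width wide
static double best_seg(const std::vector<double>& s0, int n,
                       int min_width, int* bi, int* bj) {
  const double T = s0[n];
  double best = -1.0;
  *bi = 0; *bj = n;
  for (int i = 0; i <= n - min_width; ++i) {
    if (i != 0 && i < min_width) continue;           // left piece too thin
    const int jmax = std::min(n, i + (n - min_width));
    for (int j = i + min_width; j <= jmax; ++j) {
      const int right = n - j;
      if (right != 0 && right < min_width) continue; // right piece too thin
      const int m = j - i;
      if (n - m < min_width) continue;               // rest too thin
      const double D = s0[j] - s0[i];
      const double stat = std::fabs(D * n - m * T) /
        std::sqrt((double)n * m * (n - m));
      if (stat > best) { best = stat; *bi = i; *bj = j; }
    }
  }
  return best;
}

static void cumsum0(const std::vector<double>& x, std::vector<double>& s0) {
  s0[0] = 0.0;
  for (size_t k = 0; k < x.size(); ++k) s0[k + 1] = s0[k] + x[k];
}

// [[Rcpp::export]]
List cbs_segment_test(NumericVector x, int min_width, int n_perm,
                      double alpha) {
  const int n = x.size();
  std::vector<double> xs(x.begin(), x.end());
  std::vector<double> s0(n + 1);
  cumsum0(xs, s0);
  int bi, bj;
  const double obs = best_seg(s0, n, min_width, &bi, &bj);
  if (obs < 0)
    return List::create(_["i"] = 0, _["j"] = n, _["stat"] = NA_REAL,
                        _["p"] = 1.0, _["significant"] = false,
                        _["n_perm_used"] = 0);
  // smallest count that already makes p = (1+cnt)/(1+n_perm) exceed alpha
  const int stop_count = (int)std::floor(alpha * (1.0 + n_perm));
  int cnt = 0, done = 0;
  RNGScope rng;
  std::vector<double> perm(xs);
  int pi, pj;
  for (int b = 0; b < n_perm; ++b) {
    for (int k = n - 1; k > 0; --k) {   // Fisher-Yates with R's RNG
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(perm[k], perm[idx]);
    }
    cumsum0(perm, s0);
    if (best_seg(s0, n, min_width, &pi, &pj) >= obs - 1e-12) ++cnt;
    ++done;
    if (cnt >= stop_count) break;       // cannot reach significance
  }
  const double p = (1.0 + cnt) / (1.0 + done);
  return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = obs,
                      _["p"] = p,
                      _["significant"] = (cnt < stop_count) && (p <= alpha),
                      _["n_perm_used"] = done);
}
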