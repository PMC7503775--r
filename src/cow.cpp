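#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Linear interpolation of sig at fractional position pos (0-based).
static inline double interp_at(const NumericVector& sig, double pos) {
  int n = sig.size();
  if (pos <= 0.0) return sig[0];
  if (pos >= n - 1.0) return sig[n - 1];
  int i0 = (int)std::floor(pos);
  double frac = pos - i0;
  return sig[i0] * (1.0 - frac) + sig[i0 + 1] * frac;
}

// Pearson correlation between the reference segment [rs, re] (0-based,
// inclusive) and the signal stretch [ss, se] linearly resampled onto the
// same number of points. Constant segments score 0 (not an error).
static double seg_corr(const NumericVector& sig, const NumericVector& ref,
                       int rs, int re, double ss, double se) {
  int L = re - rs;
  int n = L + 1;
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  for (int j = 0; j < n; ++j) {
    double pos = ss + (se - ss) * (double)j / (double)L;
    double x = interp_at(sig, pos);
    double y = ref[rs + j];
    sx += x; sy += y;
    sxx += x * x; syy += y * y; sxy += x * y;
  }
  double vx = sxx - sx * sx / n;
  double vy = syy - sy * sy / n;
  double cxy = sxy - sx * sy / n;
  double eps_x = 1e-12 * std::max(1.0, sxx);
  double eps_y = 1e-12 * std::max(1.0, syy);
  if (vx <= eps_x || vy <= eps_y) return 0.0;
  return cxy / std::sqrt(vx * vy);
}

// Candidate shifts ordered by increasing magnitude (0, -1, 1, -2, 2, ...):
// with strict-improvement updates this tie-breaks the DP toward the
// identity warp.
static std::vector<int> shift_order(int slack) {
  std::vector<int> out;
  out.push_back(0);
  for (int s = 1; s <= slack; ++s) {
    out.push_back(-s);
    out.push_back(s);
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List cow_dp(NumericVector signal, NumericVector reference,
            IntegerVector boundaries, int slack) {
  int K = boundaries.size() - 1;      // number of segments
  int S = 2 * slack + 1;              // states per interior node
  const double NEG = -1e30;

  // best[k][s]: best cumulative score with node k at shift (s - slack)
  std::vector<std::vector<double>> best(K + 1, std::vector<double>(S, NEG));
  std::vector<std::vector<int>> prev(K + 1, std::vector<int>(S, -1));
  std::vector<int> order = shift_order(slack);

  best[0][slack] = 0.0;  // left endpoint fixed at shift 0

  for (int k = 1; k <= K; ++k) {
    int b0 = boundaries[k - 1], b1 = boundaries[k];
    bool right_end = (k == K);
    for (int ci = 0; ci < (int)order.size(); ++ci) {
      int c = right_end ? 0 : order[ci];
      int cs = c + slack;
      for (int ai = 0; ai < (int)order.size(); ++ai) {
        int a = (k == 1) ? 0 : order[ai];
        int as = a + slack;
        if (best[k - 1][as] <= NEG / 2) { if (k == 1) break; else continue; }
        double ss = b0 + a, se = b1 + c;
        if (se <= ss) continue;                     // monotonicity
        double sc = best[k - 1][as] + seg_corr(signal, reference, b0, b1, ss, se);
        if (sc > best[k][cs] + 1e-12) {
          best[k][cs] = sc;
          prev[k][cs] = as;
        }
        if (k == 1) break;  // only shift 0 feasible at the left endpoint
      }
      if (right_end) break;
    }
  }

  // Backtrack from the fixed right endpoint.
  IntegerVector shifts(K + 1);
  shifts[K] = 0;
  int state = slack;
  double total = best[K][slack];
  for (int k = K; k >= 1; --k) {
    state = prev[k][state];
    shifts[k - 1] = state - slack;
  }

  // Build the warped signal and per-segment scores on the optimal path.
  int N = signal.size();
  NumericVector warped(N);
  NumericVector seg_scores(K);
  for (int k = 1; k <= K; ++k) {
    int b0 = boundaries[k - 1], b1 = boundaries[k];
    double ss = b0 + shifts[k - 1], se = b1 + shifts[k];
    int L = b1 - b0;
    for (int j = 0; j <= L; ++j) {
      double pos = ss + (se - ss) * (double)j / (double)L;
      warped[b0 + j] = interp_at(signal, pos);
    }
    seg_scores[k - 1] = seg_corr(signal, reference, b0, b1, ss, se);
  }

  return List::create(_["warped"] = warped,
                      _["shifts"] = shifts,
                      _["score"] = total,
                      _["segment_scores"] = seg_scores);
}
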