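#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Banded dynamic program over label pairs. State (i, j) = "ref label i matched
// to query label j"; a step from (pi, pj) skips i-pi-1 ref labels (missed in
// the query) and j-pj-1 query labels (false labels), each bounded by `band`,
// and pays a sizing penalty on the inter-label distance discrepancy; for
// discrepancies of at least `cap_from` bp (SV candidates) the penalty is
// capped at `sizing_cap` so that spanning a true SV costs a bounded amount,
// while sub-`cap_from` off-register matches pay the full weighted cost. Every
// matched pair earns `match_bonus` (without it the empty matching would be
// optimal). Leading and trailing unmatched labels are free; the best-scoring
// cell anywhere in the table ends the alignment.
// [[Rcpp::export(name = ".align_map_cpp")]]
List align_map_cpp(NumericVector ref_pos, NumericVector query_pos,
                   double miss_penalty, double false_penalty,
                   double sizing_weight, double sizing_cap,
                   double cap_from, double match_bonus, int band) {
  int n = ref_pos.size(), m = query_pos.size();
  if (n < 2 || m < 2) stop("both label maps need at least 2 labels");
  if ((double)n * (double)m > 6.4e7) stop("label maps too large for full DP");
  std::vector<double> dp((size_t)n * m);
  std::vector<int> bi((size_t)n * m, -1), bj((size_t)n * m, -1);
  double best = 0.0;
  int besti = 0, bestj = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double v = 0.0;  // fresh alignment starting at (i, j)
      int vi = -1, vj = -1;
      int pi0 = i - band - 1 < 0 ? 0 : i - band - 1;
      int pj0 = j - band - 1 < 0 ? 0 : j - band - 1;
      for (int pi = pi0; pi < i; ++pi) {
        double dr = ref_pos[i] - ref_pos[pi];
        double denom = dr > 1000.0 ? dr : 1000.0;
        double missc = miss_penalty * (i - pi - 1);
        for (int pj = pj0; pj < j; ++pj) {
          double dq = query_pos[j] - query_pos[pj];
          double ad = std::fabs(dq - dr);
          double szc = sizing_weight * ad / denom;
          double step;
          if (ad >= cap_from) {
            // SV-opening step: bounded cost that also covers the labels
            // inserted/deleted by the event (no per-label skip charges)
            step = szc > sizing_cap ? sizing_cap : szc;
          } else {
            // ordinary step: full sizing cost plus per-skip penalties, so
            // off-register matches stay expensive relative to skipping
            step = szc + missc + false_penalty * (j - pj - 1);
          }
          double cand = dp[(size_t)pi * m + pj] - step;
          if (cand > v) { v = cand; vi = pi; vj = pj; }
        }
      }
      double s = v + match_bonus;
      dp[(size_t)i * m + j] = s;
      bi[(size_t)i * m + j] = vi;
      bj[(size_t)i * m + j] = vj;
      if (s > best) { best = s; besti = i; bestj = j; }
    }
  }
  std::vector<int> ri, qi;
  int ci = besti, cj = bestj;
  while (ci >= 0 && cj >= 0) {
    ri.push_back(ci); qi.push_back(cj);
    int ni = bi[(size_t)ci * m + cj], nj = bj[(size_t)ci * m + cj];
    ci = ni; cj = nj;
  }
  std::reverse(ri.begin(), ri.end());
  std::reverse(qi.begin(), qi.end());
  return List::create(_["ref_index"] = wrap(ri), _["query_index"] = wrap(qi),
                      _["score"] = best);
}
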