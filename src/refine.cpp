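#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Local-search refinement of an open path minimizing the sum of
// adjacent weights (SARF). `order` holds 1-based indices into `w`.
// Two deterministic move neighbourhoods alternate until a full cycle
// brings no improvement:
//   * 2-opt: reverse a segment [i..j]; only the two boundary edges
//     change, so each test is O(1);
//   * or-opt: relocate a segment of 1-3 consecutive markers to another
//     position (either orientation), the standard escape from 2-opt
//     local optima on path instances.
// Moves are scanned in index order and strictly improving moves are
// applied immediately, so the result is reproducible.

static double edge(const NumericMatrix& w, int a, int b) {
  return w(a - 1, b - 1);
}

static bool pass_2opt(std::vector<int>& ord, const NumericMatrix& w) {
  const int m = ord.size();
  const double eps = 1e-12;
  bool improved = false;
  for (int i = 0; i < m - 1; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double delta = 0.0;
      if (i > 0) delta += edge(w, ord[i - 1], ord[j]) -
                          edge(w, ord[i - 1], ord[i]);
      if (j < m - 1) delta += edge(w, ord[i], ord[j + 1]) -
                              edge(w, ord[j], ord[j + 1]);
      if (delta < -eps) {
        std::reverse(ord.begin() + i, ord.begin() + j + 1);
        improved = true;
      }
    }
  }
  return improved;
}

static bool pass_oropt(std::vector<int>& ord, const NumericMatrix& w) {
  const int m = ord.size();
  const double eps = 1e-12;
  bool improved = false;
  for (int len = 1; len <= 3 && len < m; ++len) {
    for (int i = 0; i + len <= m; ++i) {
      int j = i + len - 1;            // segment [i..j]
      // cost of closing the gap left by removing the segment
      double gap = 0.0;
      if (i > 0) gap -= edge(w, ord[i - 1], ord[i]);
      if (j < m - 1) gap -= edge(w, ord[j], ord[j + 1]);
      if (i > 0 && j < m - 1) gap += edge(w, ord[i - 1], ord[j + 1]);
      for (int k = -1; k < m; ++k) {  // insert after position k
        if (k >= i - 1 && k <= j) continue;
        double ins_fwd = 0.0, ins_rev = 0.0, open = 0.0;
        if (k >= 0) {
          open -= (k + 1 < m) ? edge(w, ord[k], ord[k + 1]) : 0.0;
          ins_fwd += edge(w, ord[k], ord[i]);
          ins_rev += edge(w, ord[k], ord[j]);
        }
        if (k + 1 < m) {
          ins_fwd += edge(w, ord[j], ord[k + 1]);
          ins_rev += edge(w, ord[i], ord[k + 1]);
        }
        double base = gap + open;
        bool rev = ins_rev < ins_fwd;
        double delta = base + std::min(ins_fwd, ins_rev);
        if (delta < -eps) {
          std::vector<int> seg(ord.begin() + i, ord.begin() + j + 1);
          if (rev) std::reverse(seg.begin(), seg.end());
          ord.erase(ord.begin() + i, ord.begin() + j + 1);
          int pos = k;                // index of anchor in old ordering
          if (k > j) pos = k - len;   // segment removal shifts anchor
          ord.insert(ord.begin() + pos + 1, seg.begin(), seg.end());
          improved = true;
          // restart scan of this segment length from the left
          i = -1;
          break;
        }
      }
    }
  }
  return improved;
}

// [[Rcpp::export]]
IntegerVector refine_order_2opt(IntegerVector order, NumericMatrix w) {
  const int m = order.size();
  std::vector<int> ord(order.begin(), order.end());
  if (m < 3) return order;
  bool improved = true;
  while (improved) {
    improved = false;
    while (pass_2opt(ord, w)) improved = true;
    if (pass_oropt(ord, w)) improved = true;
  }
  return wrap(ord);
}
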