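#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen binary thinning to a one-pixel-wide skeleton. Pixels outside
// the image count as background.

static inline int px(const LogicalMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) ? 1 : 0;
}

// [[Rcpp::export(name = ".zsThin")]]
LogicalMatrix zsThin(LogicalMatrix mask) {
  LogicalMatrix m = clone(mask);
  int nr = m.nrow(), nc = m.ncol();
  std::vector<int> delR, delC;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      delR.clear(); delC.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!m(r, c)) continue;
          // neighbors clockwise from north: P2..P9
          int p[8] = {px(m, r - 1, c),     px(m, r - 1, c + 1),
                      px(m, r, c + 1),     px(m, r + 1, c + 1),
                      px(m, r + 1, c),     px(m, r + 1, c - 1),
                      px(m, r, c - 1),     px(m, r - 1, c - 1)};
          int B = 0, A = 0;
          for (int k = 0; k < 8; ++k) {
            B += p[k];
            if (!p[k] && p[(k + 1) % 8]) ++A;
          }
          if (B < 2 || B > 6 || A != 1) continue;
          bool del;
          if (step == 0)
            del = !(p[0] && p[2] && p[4]) && !(p[2] && p[4] && p[6]);
          else
            del = !(p[0] && p[2] && p[6]) && !(p[0] && p[4] && p[6]);
          if (del) { delR.push_back(r); delC.push_back(c); }
        }
      }
      if (!delR.empty()) {
        changed = true;
        for (size_t k = 0; k < delR.size(); ++k)
          m(delR[k], delC[k]) = false;
      }
    }
  }
  return m;
}
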