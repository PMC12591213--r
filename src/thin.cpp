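// Zhang-Suen topological thinning (8-connectivity preserving).
// Both sub-iterations mark pixels against the frozen current raster and
// delete simultaneously, so results are orientation-stable.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".zs_thin")]]
LogicalMatrix zs_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix m = clone(mask);
  std::vector<std::pair<int, int>> del;
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return m(r, c) ? 1 : 0;
  };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!m(r, c)) continue;
          // neighbors P2..P9 clockwise from north
          int p[8] = {at(r - 1, c), at(r - 1, c + 1), at(r, c + 1),
                      at(r + 1, c + 1), at(r + 1, c), at(r + 1, c - 1),
                      at(r, c - 1), at(r - 1, c - 1)};
          int B = 0;
          for (int i = 0; i < 8; ++i) B += p[i];
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int i = 0; i < 8; ++i) A += (p[i] == 0 && p[(i + 1) % 8] == 1);
          if (A != 1) continue;
          if (sub == 0) {
            if (p[0] && p[2] && p[4]) continue;
            if (p[2] && p[4] && p[6]) continue;
          } else {
            if (p[0] && p[2] && p[6]) continue;
            if (p[0] && p[4] && p[6]) continue;
          }
          del.push_back(std::make_pair(r, c));
        }
      }
      if (!del.empty()) {
        changed = true;
        for (std::size_t i = 0; i < del.size(); ++i)
          m(del[i].first, del[i].second) = false;
      }
    }
  }
  return m;
}
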