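#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labelling of a binary matrix by breadth-first
// search. Returns an integer matrix: 0 background, components numbered
// 1..K in raster order of their first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + nr * c);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int qr = pr + dr, qc = pc + dc;
            if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
            if (mask(qr, qc) && lab(qr, qc) == 0) {
              lab(qr, qc) = next;
              stack.push_back(qr + nr * qc);
            }
          }
        }
      }
    }
  }
  return lab;
}
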