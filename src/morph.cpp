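#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a logical mask.
// Labels are 1..k in scan order (column-major, matching R matrices);
// background (FALSE) pixels get 0. connectivity is 4 or 8.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix lab(nr, nc);
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 4 ? dr4 : dr8;
  const int *dc = connectivity == 4 ? dc4 : dc8;
  const int nnb = connectivity;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc0 = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = cr + dr[k], c2 = cc0 + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Binary dilation by a Euclidean disc of the given radius (in pixels).
// radius 0 returns the mask unchanged.
// [[Rcpp::export(name = ".dilate_disc")]]
LogicalMatrix dilate_disc(LogicalMatrix mask, int radius) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  if (radius < 0) stop("radius must be >= 0");
  // precompute disc offsets
  std::vector<int> offr, offc;
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      if (dr * dr + dc * dc <= radius * radius) {
        offr.push_back(dr);
        offc.push_back(dc);
      }
  const int no = (int)offr.size();
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      for (int k = 0; k < no; ++k) {
        int r2 = r + offr[k], c2 = c + offc[k];
        if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc) out(r2, c2) = true;
      }
    }
  }
  return out;
}
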