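#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a logical mask by breadth-first search.
// connectivity: 4 (edge neighbors) or 8 (edge + diagonal neighbors).
// Labels are assigned in raster-scan order of each component's first pixel,
// so they are consecutive 1..n and deterministic.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(LogicalMatrix m, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nnb; ++k) {
          int qi = pi + dr8[k], qj = pj + dc8[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (m(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  lab.attr("n_objects") = next;
  return lab;
}

// Fill interior holes: background components (4-connectivity) that do not
// touch the image border become foreground.
// [[Rcpp::export(name = ".fill_holes_cpp")]]
LogicalMatrix fill_holes_cpp(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<char> outside(static_cast<size_t>(nr) * nc, 0);
  std::vector<int> stack;
  // flood the border-connected background under 4-connectivity
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (i != 0 && i != nr - 1 && j != 0 && j != nc - 1) continue;
      if (m(i, j) || outside[i + (size_t)j * nr]) continue;
      outside[i + (size_t)j * nr] = 1;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int qi = pi + dr[k], qj = pj + dc[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          size_t q = qi + (size_t)qj * nr;
          if (!m(qi, qj) && !outside[q]) {
            outside[q] = 1;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = m(i, j) || !outside[i + (size_t)j * nr];
  return out;
}
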