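#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a logical mask by breadth-first search.
// connectivity: 4 (edge neighbours) or 8 (edge + corner neighbours).
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity = 8) {
  int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  int next_label = 0;
  std::vector<int> stack;
  const int dy8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[] = {-1, 0, 0, 1};
  const int dx4[] = {0, -1, 1, 0};
  const int *dy = (connectivity == 8) ? dy8 : dy4;
  const int *dx = (connectivity == 8) ? dx8 : dx4;
  int nn = (connectivity == 8) ? 8 : 4;

  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next_label;
      stack.clear();
      stack.push_back(y + x * ny);
      lab(y, x) = next_label;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cy = idx % ny, cx = idx / ny;
        for (int k = 0; k < nn; ++k) {
          int yy = cy + dy[k], xx = cx + dx[k];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (mask(yy, xx) && lab(yy, xx) == 0) {
            lab(yy, xx) = next_label;
            stack.push_back(yy + xx * ny);
          }
        }
      }
    }
  }
  return lab;
}

// Grayscale erosion/dilation with a non-flat structuring element.
// se holds SE heights, se_on marks the SE support; both odd-sized and
// centred. Pixels outside the image do not constrain the extremum.
// [[Rcpp::export]]
NumericMatrix cpp_morph(NumericMatrix img, NumericMatrix se,
                        LogicalMatrix se_on, bool erode) {
  int ny = img.nrow(), nx = img.ncol();
  int sy = se.nrow(), sx = se.ncol();
  int cy = sy / 2, cx = sx / 2;
  NumericMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      double best = erode ? R_PosInf : R_NegInf;
      for (int j = 0; j < sx; ++j) {
        int xx = x + (j - cx);
        if (xx < 0 || xx >= nx) continue;
        for (int i = 0; i < sy; ++i) {
          if (!se_on(i, j)) continue;
          int yy = y + (i - cy);
          if (yy < 0 || yy >= ny) continue;
          double v = erode ? img(yy, xx) - se(i, j) : img(yy, xx) + se(i, j);
          if (erode ? (v < best) : (v > best)) best = v;
        }
      }
      out(y, x) = best;
    }
  }
  return out;
}
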