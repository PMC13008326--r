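#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int cell_index(double v, double cs, int R) {
  int k = (int)std::floor(v / cs + 0.5);
  if (k < 0) k = 0;
  if (k > R - 1) k = R - 1;
  return k;
}

// Supercover traversal of polylines on a grid of R x R cells with spacing
// `cs`, cell k centered at k*cs (covering [k*cs - cs/2, k*cs + cs/2)).
// Points with equal `group` are joined by segments; traversal steps one
// axis at a time so each segment yields a 4-connected chain of cells.
// Returns an integer matrix of 0-based (ix, iy) cell indices (with repeats).
// [[Rcpp::export]]
IntegerMatrix supercover_cells(NumericVector x, NumericVector y,
                               IntegerVector group, double cs, int R) {
  const int n = x.size();
  std::vector<int> out_i, out_j;
  out_i.reserve(4 * n);
  out_j.reserve(4 * n);
  for (int s = 0; s < n; ++s) {
    int ix = cell_index(x[s], cs, R), iy = cell_index(y[s], cs, R);
    out_i.push_back(ix);
    out_j.push_back(iy);
    if (s + 1 >= n || group[s + 1] != group[s]) continue;
    double x0 = x[s], y0 = y[s], x1 = x[s + 1], y1 = y[s + 1];
    int tx = cell_index(x1, cs, R), ty = cell_index(y1, cs, R);
    double dx = x1 - x0, dy = y1 - y0;
    int stepx = dx > 0 ? 1 : -1, stepy = dy > 0 ? 1 : -1;
    // parametric distance to the next vertical/horizontal cell boundary
    double tMaxX = R_PosInf, tMaxY = R_PosInf, tDeltaX = R_PosInf, tDeltaY = R_PosInf;
    if (dx != 0) {
      double bx = (ix + 0.5 * stepx) * cs;  // next boundary crossed in x
      tMaxX = (bx - x0) / dx;
      tDeltaX = cs / std::fabs(dx);
    }
    if (dy != 0) {
      double by = (iy + 0.5 * stepy) * cs;
      tMaxY = (by - y0) / dy;
      tDeltaY = cs / std::fabs(dy);
    }
    int guard = 4 * R;  // a segment can cross at most ~2R boundaries
    while ((ix != tx || iy != ty) && guard-- > 0) {
      if (tMaxX <= tMaxY) {
        ix += stepx;
        tMaxX += tDeltaX;
      } else {
        iy += stepy;
        tMaxY += tDeltaY;
      }
      if (ix < 0) ix = 0;
      if (ix > R - 1) ix = R - 1;
      if (iy < 0) iy = 0;
      if (iy > R - 1) iy = R - 1;
      out_i.push_back(ix);
      out_j.push_back(iy);
    }
  }
  IntegerMatrix out(out_i.size(), 2);
  for (size_t t = 0; t < out_i.size(); ++t) {
    out(t, 0) = out_i[t];
    out(t, 1) = out_j[t];
  }
  return out;
}
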