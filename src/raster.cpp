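#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Conservative (supercover) rasterization of a polyline onto a G x G grid.
// Marks every cell whose closed unit square is touched by a segment, via
// Amanatides-Woo voxel traversal. Input coordinates are continuous grid
// coordinates in [0, G); cell (r, c) covers [c, c+1) x [r, r+1).

static inline int cell_of(double v, int G) {
  int c = (int)std::floor(v);
  if (c < 0) c = 0;
  if (c >= G) c = G - 1;
  return c;
}

// [[Rcpp::export]]
LogicalMatrix raster_supercover_cpp(NumericVector px, NumericVector py, int G) {
  int n = px.size();
  if (n < 1) stop("empty point set");
  LogicalMatrix occ(G, G); // row = y cell, col = x cell
  // mark sample cells
  for (int i = 0; i < n; ++i) occ(cell_of(py[i], G), cell_of(px[i], G)) = true;

  for (int i = 0; i + 1 < n; ++i) {
    double x0 = px[i], y0 = py[i], x1 = px[i + 1], y1 = py[i + 1];
    int cx = cell_of(x0, G), cy = cell_of(y0, G);
    int ex = cell_of(x1, G), ey = cell_of(y1, G);
    double dx = x1 - x0, dy = y1 - y0;
    int stepX = (dx > 0) - (dx < 0);
    int stepY = (dy > 0) - (dy < 0);
    double tMaxX = R_PosInf, tMaxY = R_PosInf, tDeltaX = R_PosInf,
           tDeltaY = R_PosInf;
    if (stepX != 0) {
      double nb = (stepX > 0) ? (cx + 1.0) : (double)cx;
      tMaxX = (nb - x0) / dx;
      tDeltaX = 1.0 / std::fabs(dx);
    }
    if (stepY != 0) {
      double nb = (stepY > 0) ? (cy + 1.0) : (double)cy;
      tMaxY = (nb - y0) / dy;
      tDeltaY = 1.0 / std::fabs(dy);
    }
    int guard = 4 * G + 8;
    while ((cx != ex || cy != ey) && guard-- > 0) {
      if (tMaxX < tMaxY) {
        cx += stepX;
        tMaxX += tDeltaX;
      } else if (tMaxY < tMaxX) {
        cy += stepY;
        tMaxY += tDeltaY;
      } else { // exact corner crossing: step both (diagonal pass-through)
        cx += stepX;
        cy += stepY;
        tMaxX += tDeltaX;
        tMaxY += tDeltaY;
      }
      if (cx < 0 || cx >= G || cy < 0 || cy >= G) break;
      occ(cy, cx) = true;
    }
  }
  return occ;
}
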