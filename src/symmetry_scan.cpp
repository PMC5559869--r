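#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sample of a binary mask stored as a numeric matrix (row = y,
// col = x, both 1-based continuous coordinates). Outside the grid -> 0.
static inline double bilinear(const NumericMatrix &m, double x, double y) {
  const int nr = m.nrow(), nc = m.ncol();
  if (x < 1.0 || x > (double)nc || y < 1.0 || y > (double)nr) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 >= nc) x0 = nc - 1;
  if (y0 >= nr) y0 = nr - 1;
  const double fx = x - x0, fy = y - y0;
  const double v00 = m(y0 - 1, x0 - 1);
  const double v01 = (x0 < nc) ? m(y0 - 1, x0) : 0.0;
  const double v10 = (y0 < nr) ? m(y0, x0 - 1) : 0.0;
  const double v11 = (x0 < nc && y0 < nr) ? m(y0, x0) : 0.0;
  return v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
         v10 * (1 - fx) * fy + v11 * fx * fy;
}

// Mirror-overlap symmetry ratio area(S intersect mirror(S)) / area(S) for a
// set of candidate axes through (cx, cy). Angles are in radians, measured
// clockwise from the +y (anteroposterior) direction, so the axis unit vector
// in (x, y) pixel coordinates is (sin a, cos a). The reflection is performed
// in continuous coordinates and the mirrored mask value is read bilinearly,
// which avoids pixel-grid axis bias.
// [[Rcpp::export]]
NumericVector cpp_symmetry_scan(const NumericMatrix &mask,
                                const NumericVector &angles,
                                double cx, double cy) {
  const int nr = mask.nrow(), nc = mask.ncol(), na = angles.size();
  std::vector<double> px, py;
  px.reserve(256); py.reserve(256);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j) > 0.5) { px.push_back(j + 1.0); py.push_back(i + 1.0); }
  const int n = (int)px.size();
  NumericVector out(na);
  if (n == 0) { out.fill(NA_REAL); return out; }
  for (int k = 0; k < na; ++k) {
    const double ux = std::sin(angles[k]), uy = std::cos(angles[k]);
    double acc = 0.0;
    for (int p = 0; p < n; ++p) {
      const double dx = px[p] - cx, dy = py[p] - cy;
      const double pr = dx * ux + dy * uy;
      const double rx = 2.0 * pr * ux - dx, ry = 2.0 * pr * uy - dy;
      acc += bilinear(mask, cx + rx, cy + ry);
    }
    out[k] = acc / n;
  }
  return out;
}

// Even-odd (crossing number) polygon fill on a pixel grid. Pixel (i, j)
// [row i = y, col j = x, 1-based] has centre x = x0 + (j-1)*spacing,
// y = y0 + (i-1)*spacing. Vertices in mm; the polygon is implicitly closed.
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize_polygon(const NumericVector &vx,
                                    const NumericVector &vy,
                                    double x0, double y0, double spacing,
                                    int nx, int ny) {
  const int nv = vx.size();
  LogicalMatrix out(ny, nx);
  for (int i = 0; i < ny; ++i) {
    const double yc = y0 + i * spacing;
    // collect x-crossings of polygon edges with this scanline
    std::vector<double> xs;
    for (int a = 0; a < nv; ++a) {
      const int b = (a + 1) % nv;
      const double ya = vy[a], yb = vy[b];
      if ((ya <= yc && yb > yc) || (yb <= yc && ya > yc)) {
        const double t = (yc - ya) / (yb - ya);
        xs.push_back(vx[a] + t * (vx[b] - vx[a]));
      }
    }
    std::sort(xs.begin(), xs.end());
    // fill alternate spans
    for (size_t s = 0; s + 1 < xs.size(); s += 2) {
      int j0 = (int)std::ceil((xs[s] - x0) / spacing);
      int j1 = (int)std::floor((xs[s + 1] - x0) / spacing);
      if (j0 < 0) j0 = 0;
      if (j1 > nx - 1) j1 = nx - 1;
      for (int j = j0; j <= j1; ++j) out(i, j) = true;
    }
  }
  return out;
}
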