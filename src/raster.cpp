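#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Z-buffered triangle rasteriser with perspective-correct attribute
// interpolation.  Vertices are camera-frame (x right, y down, z forward, mm);
// pixel centres sit at integer coordinates, image origin top-left.
//
// V: n x 3 camera-frame vertices; F: m x 3 one-based vertex indices;
// A: n x k per-vertex attributes (interpolated perspective-correctly).
// Returns depth (h x w, NA where empty), face (h x w, 0 where empty) and the
// interpolated attribute planes as an h x w x k array.
// [[Rcpp::export]]
List raster_mesh_cpp(NumericMatrix V, IntegerMatrix F, NumericMatrix A,
                     double fx, double fy, double cx, double cy,
                     int width, int height, double znear = 1e-3) {
  const int nf = F.nrow(), k = A.ncol();
  NumericMatrix depth(height, width);
  IntegerMatrix face(height, width);
  std::fill(depth.begin(), depth.end(), NA_REAL);
  NumericVector attr(static_cast<R_xlen_t>(height) * width * k, NA_REAL);
  std::vector<double> zbuf(static_cast<size_t>(height) * width,
                           std::numeric_limits<double>::infinity());

  for (int f = 0; f < nf; ++f) {
    const int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    const double z0 = V(i0, 2), z1 = V(i1, 2), z2 = V(i2, 2);
    if (z0 <= znear || z1 <= znear || z2 <= znear) continue;
    const double x0 = fx * V(i0, 0) / z0 + cx, y0 = fy * V(i0, 1) / z0 + cy;
    const double x1 = fx * V(i1, 0) / z1 + cx, y1 = fy * V(i1, 1) / z1 + cy;
    const double x2 = fx * V(i2, 0) / z2 + cx, y2 = fy * V(i2, 1) / z2 + cy;
    const double area = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (std::fabs(area) < 1e-12) continue;
    int xmin = std::max(0, (int)std::ceil(std::min({x0, x1, x2})));
    int xmax = std::min(width - 1, (int)std::floor(std::max({x0, x1, x2})));
    int ymin = std::max(0, (int)std::ceil(std::min({y0, y1, y2})));
    int ymax = std::min(height - 1, (int)std::floor(std::max({y0, y1, y2})));
    if (xmin > xmax || ymin > ymax) continue;
    const double w0i = 1.0 / z0, w1i = 1.0 / z1, w2i = 1.0 / z2;
    for (int py = ymin; py <= ymax; ++py) {
      for (int px = xmin; px <= xmax; ++px) {
        double b0 = ((x1 - px) * (y2 - py) - (x2 - px) * (y1 - py)) / area;
        double b1 = ((x2 - px) * (y0 - py) - (x0 - px) * (y2 - py)) / area;
        double b2 = 1.0 - b0 - b1;
        if (b0 < 0 || b1 < 0 || b2 < 0) continue;
        const double winv = b0 * w0i + b1 * w1i + b2 * w2i;
        const double z = 1.0 / winv;
        const size_t idx = static_cast<size_t>(px) * height + py;
        if (z >= zbuf[idx]) continue;
        zbuf[idx] = z;
        depth(py, px) = z;
        face(py, px) = f + 1;
        for (int a = 0; a < k; ++a) {
          const double val = (b0 * A(i0, a) * w0i + b1 * A(i1, a) * w1i +
                              b2 * A(i2, a) * w2i) * z;
          attr[static_cast<R_xlen_t>(a) * height * width + idx] = val;
        }
      }
    }
  }
  attr.attr("dim") = IntegerVector::create(height, width, k);
  return List::create(_["depth"] = depth, _["face"] = face, _["attr"] = attr);
}
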