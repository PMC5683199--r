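#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Full shaded render of the synthetic scene for one camera view: z-buffered
// rasterisation with per-pixel Phong shading, a spot light co-located with
// the main camera, quadratic distance falloff, and bilinear albedo lookup
// from a texture grid indexed by world (x, y).  Returns the 8-bit image,
// the depth map (camera z, mm) and the saturated-specular mask.
// [[Rcpp::export]]
List render_view_cpp(NumericMatrix V, IntegerMatrix F, NumericMatrix N,
                     NumericMatrix tex, double tex_x0, double tex_y0,
                     double tex_dx,
                     NumericMatrix Rcw, NumericVector tcw, double bx,
                     double fx, double fy, double cx, double cy,
                     int width, int height,
                     NumericVector light_pos, NumericVector light_axis,
                     double spec_strength, double shininess,
                     double ambient, double diffuse_gain,
                     double falloff_d0, double spot_exp,
                     double znear = 1.0) {
  const int nv = V.nrow(), nf = F.nrow();
  const int ntx = tex.nrow(), nty = tex.ncol();
  NumericMatrix image(height, width), depth(height, width);
  LogicalMatrix smask(height, width);
  std::fill(depth.begin(), depth.end(), NA_REAL);
  std::vector<double> zbuf(static_cast<size_t>(height) * width,
                           std::numeric_limits<double>::infinity());
  // camera-frame vertices and screen coords
  std::vector<double> Xc(nv), Yc(nv), Zc(nv), Sx(nv), Sy(nv);
  double R00 = Rcw(0, 0), R01 = Rcw(0, 1), R02 = Rcw(0, 2);
  double R10 = Rcw(1, 0), R11 = Rcw(1, 1), R12 = Rcw(1, 2);
  double R20 = Rcw(2, 0), R21 = Rcw(2, 1), R22 = Rcw(2, 2);
  for (int i = 0; i < nv; ++i) {
    double dx = V(i, 0) - tcw[0], dy = V(i, 1) - tcw[1], dz = V(i, 2) - tcw[2];
    // camera frame: R^T (X - t)
    double xc = R00 * dx + R10 * dy + R20 * dz - bx;
    double yc = R01 * dx + R11 * dy + R21 * dz;
    double zc = R02 * dx + R12 * dy + R22 * dz;
    Xc[i] = xc; Yc[i] = yc; Zc[i] = zc;
    if (zc > znear) {
      Sx[i] = fx * xc / zc + cx;
      Sy[i] = fy * yc / zc + cy;
    }
  }
  // view-camera centre in world coordinates
  double camx = tcw[0] + Rcw(0, 0) * bx;
  double camy = tcw[1] + Rcw(1, 0) * bx;
  double camz = tcw[2] + Rcw(2, 0) * bx;
  const double lx = light_pos[0], ly = light_pos[1], lz = light_pos[2];
  const double ax = light_axis[0], ay = light_axis[1], az = light_axis[2];

  for (int f = 0; f < nf; ++f) {
    const int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    if (Zc[i0] <= znear || Zc[i1] <= znear || Zc[i2] <= znear) continue;
    const double x0 = Sx[i0], y0 = Sy[i0], x1 = Sx[i1], y1 = Sy[i1],
                 x2 = Sx[i2], y2 = Sy[i2];
    const double area = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (std::fabs(area) < 1e-12) continue;
    int xmin = std::max(0, (int)std::ceil(std::min({x0, x1, x2})));
    int xmax = std::min(width - 1, (int)std::floor(std::max({x0, x1, x2})));
    int ymin = std::max(0, (int)std::ceil(std::min({y0, y1, y2})));
    int ymax = std::min(height - 1, (int)std::floor(std::max({y0, y1, y2})));
    if (xmin > xmax || ymin > ymax) continue;
    const double w0 = 1.0 / Zc[i0], w1 = 1.0 / Zc[i1], w2 = 1.0 / Zc[i2];
    for (int py = ymin; py <= ymax; ++py) {
      for (int px = xmin; px <= xmax; ++px) {
        double b0 = ((x1 - px) * (y2 - py) - (x2 - px) * (y1 - py)) / area;
        double b1 = ((x2 - px) * (y0 - py) - (x0 - px) * (y2 - py)) / area;
        double b2 = 1.0 - b0 - b1;
        if (b0 < 0 || b1 < 0 || b2 < 0) continue;
        const double winv = b0 * w0 + b1 * w1 + b2 * w2;
        const double z = 1.0 / winv;
        const size_t idx = static_cast<size_t>(px) * height + py;
        if (z >= zbuf[idx]) continue;
        zbuf[idx] = z;
        const double c0 = b0 * w0 * z, c1 = b1 * w1 * z, c2 = b2 * w2 * z;
        // world position and normal (perspective-correct)
        double wx = c0 * V(i0, 0) + c1 * V(i1, 0) + c2 * V(i2, 0);
        double wy = c0 * V(i0, 1) + c1 * V(i1, 1) + c2 * V(i2, 1);
        double wz = c0 * V(i0, 2) + c1 * V(i1, 2) + c2 * V(i2, 2);
        double nx = c0 * N(i0, 0) + c1 * N(i1, 0) + c2 * N(i2, 0);
        double ny = c0 * N(i0, 1) + c1 * N(i1, 1) + c2 * N(i2, 1);
        double nz = c0 * N(i0, 2) + c1 * N(i1, 2) + c2 * N(i2, 2);
        double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
        if (nn < 1e-12) continue;
        nx /= nn; ny /= nn; nz /= nn;
        // albedo from the texture grid (bilinear, clamped)
        double tx = (wx - tex_x0) / tex_dx, ty = (wy - tex_y0) / tex_dx;
        if (tx < 0) tx = 0; if (tx > ntx - 1.000001) tx = ntx - 1.000001;
        if (ty < 0) ty = 0; if (ty > nty - 1.000001) ty = nty - 1.000001;
        int ti = (int)tx, tj = (int)ty;
        double ftx = tx - ti, fty = ty - tj;
        double albedo =
            (1 - ftx) * ((1 - fty) * tex(ti, tj) + fty * tex(ti, tj + 1)) +
            ftx * ((1 - fty) * tex(ti + 1, tj) + fty * tex(ti + 1, tj + 1));
        // lighting
        double ldx = lx - wx, ldy = ly - wy, ldz = lz - wz;
        double dist = std::sqrt(ldx * ldx + ldy * ldy + ldz * ldz);
        ldx /= dist; ldy /= dist; ldz /= dist;
        double ndotl = std::max(0.0, nx * ldx + ny * ldy + nz * ldz);
        double spot = std::max(0.0, -(ldx * ax + ldy * ay + ldz * az));
        spot = std::pow(spot, spot_exp);
        double falloff = 1.0 / (1.0 + (dist / falloff_d0) * (dist / falloff_d0));
        double vdx = camx - wx, vdy = camy - wy, vdz = camz - wz;
        double vn = std::sqrt(vdx * vdx + vdy * vdy + vdz * vdz);
        vdx /= vn; vdy /= vn; vdz /= vn;
        double hx = ldx + vdx, hy = ldy + vdy, hz = ldz + vdz;
        double hn = std::sqrt(hx * hx + hy * hy + hz * hz);
        double ndoth = hn < 1e-12 ? 0 : std::max(0.0, (nx * hx + ny * hy + nz * hz) / hn);
        double spec = spec_strength * std::pow(ndoth, shininess) * falloff * spot;
        double inten = 255.0 * (albedo * (ambient + diffuse_gain * ndotl *
                                          falloff * spot) + spec);
        double iv = std::round(std::min(255.0, std::max(0.0, inten)));
        image(py, px) = iv;
        depth(py, px) = z;
        smask(py, px) = (255.0 * spec > 10.0) && iv > 240.0;
      }
    }
  }
  return List::create(_["image"] = image, _["depth"] = depth,
                      _["specular_mask"] = smask);
}
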