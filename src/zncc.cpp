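#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Patch-based ZNCC cost volume over a rectified stereo pair.
// C(p, d) compares the square patch N_p centred on pixel p in the left image
// with the patch centred on p - d (horizontal shift) in the right image:
//
//   zncc = sum((L - Lbar)(R - Rbar)) / sqrt(sum((L - Lbar)^2) sum((R - Rbar)^2))
//
// The stored cost is the negated correlation (lower = better).  Window sums
// are computed with integral images, one shift per disparity.  Pixels whose
// window leaves either image, or whose patch variance vanishes, are NA.
// [[Rcpp::export]]
NumericVector zncc_volume_cpp(NumericMatrix L, NumericMatrix R,
                              int dmin, int dmax, int radius) {
  const int h = L.nrow(), w = L.ncol(), nd = dmax - dmin + 1;
  const int win = 2 * radius + 1, npix = win * win;
  const double eps = 1e-8;
  NumericVector vol(static_cast<R_xlen_t>(h) * w * nd, NA_REAL);

  // integral images (h+1) x (w+1), column-major [x * (h+1) + y]
  auto integral = [&](const double *src, std::vector<double> &dst, bool sq) {
    dst.assign(static_cast<size_t>(w + 1) * (h + 1), 0.0);
    for (int x = 1; x <= w; ++x)
      for (int y = 1; y <= h; ++y) {
        double v = src[static_cast<size_t>(x - 1) * h + (y - 1)];
        if (sq) v *= v;
        dst[static_cast<size_t>(x) * (h + 1) + y] =
            v + dst[static_cast<size_t>(x - 1) * (h + 1) + y] +
            dst[static_cast<size_t>(x) * (h + 1) + y - 1] -
            dst[static_cast<size_t>(x - 1) * (h + 1) + y - 1];
      }
  };
  auto win_sum = [&](const std::vector<double> &ii, int x, int y) {
    // sum over [x-radius, x+radius] x [y-radius, y+radius], 0-based pixel coords
    int x0 = x - radius, x1 = x + radius + 1, y0 = y - radius, y1 = y + radius + 1;
    return ii[static_cast<size_t>(x1) * (h + 1) + y1] -
           ii[static_cast<size_t>(x0) * (h + 1) + y1] -
           ii[static_cast<size_t>(x1) * (h + 1) + y0] +
           ii[static_cast<size_t>(x0) * (h + 1) + y0];
  };

  std::vector<double> Lc(static_cast<size_t>(w) * h), Rc(Lc.size()), LRprod(Lc.size());
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      Lc[static_cast<size_t>(x) * h + y] = L(y, x);
      Rc[static_cast<size_t>(x) * h + y] = R(y, x);
    }
  std::vector<double> iL, iL2, iR, iR2, iLR;
  integral(Lc.data(), iL, false);
  integral(Lc.data(), iL2, true);
  integral(Rc.data(), iR, false);
  integral(Rc.data(), iR2, true);

  // disparity-independent window sums, precomputed once per image
  std::vector<double> SL(Lc.size()), SL2(Lc.size()), SR(Lc.size()),
      SR2(Lc.size());
  for (int x = radius; x < w - radius; ++x)
    for (int y = radius; y < h - radius; ++y) {
      size_t k = static_cast<size_t>(x) * h + y;
      SL[k] = win_sum(iL, x, y);
      SL2[k] = win_sum(iL2, x, y);
      SR[k] = win_sum(iR, x, y);
      SR2[k] = win_sum(iR2, x, y);
    }

  for (int di = 0; di < nd; ++di) {
    const int d = dmin + di;
    // product image L(x, y) * R(x - d, y)
    for (int x = d; x < w; ++x) {
      const double *lc = &Lc[static_cast<size_t>(x) * h];
      const double *rc = &Rc[static_cast<size_t>(x - d) * h];
      double *pr = &LRprod[static_cast<size_t>(x) * h];
      for (int y = 0; y < h; ++y) pr[y] = lc[y] * rc[y];
    }
    for (int x = 0; x < std::min(d, w); ++x)
      std::fill(&LRprod[static_cast<size_t>(x) * h],
                &LRprod[static_cast<size_t>(x) * h] + h, 0.0);
    integral(LRprod.data(), iLR, false);
    for (int x = std::max(radius, d + radius); x < w - radius; ++x) {
      int xr = x - d;
      for (int y = radius; y < h - radius; ++y) {
        size_t kL = static_cast<size_t>(x) * h + y;
        size_t kR = static_cast<size_t>(xr) * h + y;
        double sL = SL[kL], sL2 = SL2[kL];
        double sR = SR[kR], sR2 = SR2[kR];
        double sLR = win_sum(iLR, x, y);
        double varL = sL2 - sL * sL / npix;
        double varR = sR2 - sR * sR / npix;
        if (varL < eps || varR < eps) continue;
        double num = sLR - sL * sR / npix;
        double z = num / std::sqrt(varL * varR);
        if (z > 1.0) z = 1.0;
        if (z < -1.0) z = -1.0;
        vol[static_cast<R_xlen_t>(di) * h * w +
            static_cast<R_xlen_t>(x) * h + y] = -z;
      }
    }
  }
  vol.attr("dim") = IntegerVector::create(h, w, nd);
  return vol;
}
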