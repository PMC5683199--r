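#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Winner-takes-all disparity selection with optional parabolic sub-pixel
// refinement; ties break toward the smaller disparity.
// [[Rcpp::export]]
List wta_cpp(NumericVector vol, int h, int w, int dmin, bool subpixel) {
  const int nd = vol.size() / (static_cast<R_xlen_t>(h) * w);
  NumericMatrix disp(h, w);
  LogicalMatrix valid(h, w);
  const R_xlen_t plane = static_cast<R_xlen_t>(h) * w;
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      const R_xlen_t base = static_cast<R_xlen_t>(x) * h + y;
      double best = R_PosInf;
      int bi = -1;
      for (int d = 0; d < nd; ++d) {
        double c = vol[base + plane * d];
        if (R_IsNA(c) || !R_finite(c)) continue;
        if (c < best) { best = c; bi = d; }
      }
      if (bi < 0) {
        disp(y, x) = NA_REAL;
        valid(y, x) = false;
        continue;
      }
      valid(y, x) = true;
      double dd = dmin + bi;
      if (subpixel && bi > 0 && bi < nd - 1) {
        double cm = vol[base + plane * (bi - 1)];
        double cp = vol[base + plane * (bi + 1)];
        if (R_finite(cm) && R_finite(cp)) {
          double den = cm - 2 * best + cp;
          if (den > 1e-12) {
            double delta = 0.5 * (cm - cp) / den;
            if (delta > 0.5) delta = 0.5;
            if (delta < -0.5) delta = -0.5;
            dd += delta;
          }
        }
      }
      disp(y, x) = dd;
    }
  }
  return List::create(_["disparity"] = disp, _["valid"] = valid);
}

// Median-deviation speckle filter: invalidate pixels whose disparity
// deviates from the local window median by more than `tol` px (isolated
// false matches survive both WTA and variational smoothing).
// [[Rcpp::export]]
List median_filter_cpp(NumericMatrix disp, LogicalMatrix valid, int radius,
                       double tol) {
  const int h = disp.nrow(), w = disp.ncol();
  NumericMatrix out(h, w);
  LogicalMatrix vout(h, w);
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      out(y, x) = disp(y, x);
      vout(y, x) = valid(y, x);
      if (!valid(y, x)) continue;
      buf.clear();
      for (int dx = -radius; dx <= radius; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= w) continue;
        for (int dy = -radius; dy <= radius; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= h) continue;
          if (valid(yy, xx)) buf.push_back(disp(yy, xx));
        }
      }
      if (buf.size() < 4) { vout(y, x) = false; out(y, x) = NA_REAL; continue; }
      size_t mid = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      if (std::fabs(disp(y, x) - buf[mid]) > tol) {
        vout(y, x) = false;
        out(y, x) = NA_REAL;
      }
    }
  return List::create(_["disparity"] = out, _["valid"] = vout);
}

static inline double huber_pen(double t, double eps) {
  double a = std::fabs(t);
  return a <= eps ? t * t / (2 * eps) : a - eps / 2;
}

// Huber-L1 variational smoothing by projected gradient descent with
// backtracking on the total energy (monotone descent by construction).
// vol: cost volume (h, w, nd) with NA treated as the worst cost; u0: the
// WTA initialisation (invalids pre-filled); gx, gy: edge weights.
// [[Rcpp::export]]
List huber_l1_smooth_cpp(NumericVector vol, int h, int w, int dmin, int dmax,
                         NumericMatrix u0, LogicalMatrix valid,
                         NumericMatrix gx, NumericMatrix gy,
                         double lambda, double eps, int iterations) {
  const int nd = dmax - dmin + 1;
  const R_xlen_t plane = static_cast<R_xlen_t>(h) * w;
  std::vector<double> M(plane * nd);
  for (R_xlen_t k = 0; k < plane * nd; ++k) {
    double c = vol[k];
    M[k] = (R_IsNA(c) || !R_finite(c)) ? 1.0 : c;
  }
  auto sample = [&](R_xlen_t px, double u) {
    if (u < dmin) u = dmin;
    if (u > dmax) u = dmax;
    int k0 = (int)(u - dmin);
    if (k0 > nd - 2) k0 = nd - 2;
    double frac = u - (dmin + k0);
    return (1 - frac) * M[px + plane * k0] + frac * M[px + plane * (k0 + 1)];
  };
  std::vector<double> u(u0.begin(), u0.end()), unew(u.size()), g(u.size());
  auto energy = [&](const std::vector<double> &uu) {
    double E = 0;
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y) {
        R_xlen_t k = static_cast<R_xlen_t>(x) * h + y;
        if (x + 1 < w) E += gx(y, x) * huber_pen(uu[k + h] - uu[k], eps);
        if (y + 1 < h) E += gy(y, x) * huber_pen(uu[k + 1] - uu[k], eps);
        if (valid(y, x)) E += lambda * sample(k, uu[k]);
      }
    return E;
  };
  double E = energy(u);
  const double E0 = E;
  double step = 0.25;
  const double dstep = 0.5;
  for (int it = 0; it < iterations; ++it) {
    // gradient of the smoothness term (flux differences) + data slope
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y) {
        R_xlen_t k = static_cast<R_xlen_t>(x) * h + y;
        double gr = 0;
        if (x + 1 < w) {
          double t = u[k + h] - u[k];
          double f = gx(y, x) * (std::fabs(t) <= eps ? t / eps
                                                     : (t > 0 ? 1.0 : -1.0));
          gr -= f;
        }
        if (x > 0) {
          double t = u[k] - u[k - h];
          double f = gx(y, x - 1) * (std::fabs(t) <= eps ? t / eps
                                                         : (t > 0 ? 1.0 : -1.0));
          gr += f;
        }
        if (y + 1 < h) {
          double t = u[k + 1] - u[k];
          double f = gy(y, x) * (std::fabs(t) <= eps ? t / eps
                                                     : (t > 0 ? 1.0 : -1.0));
          gr -= f;
        }
        if (y > 0) {
          double t = u[k] - u[k - 1];
          double f = gy(y - 1, x) * (std::fabs(t) <= eps ? t / eps
                                                         : (t > 0 ? 1.0 : -1.0));
          gr += f;
        }
        if (valid(y, x)) {
          gr += lambda * (sample(k, u[k] + dstep) - sample(k, u[k] - dstep)) /
                (2 * dstep);
        }
        g[k] = gr;
      }
    bool moved = false;
    for (int tries = 0; tries < 6; ++tries) {
      for (size_t k = 0; k < u.size(); ++k) {
        double v = u[k] - step * g[k];
        if (v < dmin) v = dmin;
        if (v > dmax) v = dmax;
        unew[k] = v;
      }
      double En = energy(unew);
      if (En <= E) {
        u.swap(unew);
        E = En;
        step *= 1.2;
        moved = true;
        break;
      }
      step /= 2;
    }
    if (!moved) break;
  }
  NumericMatrix out(h, w);
  std::copy(u.begin(), u.end(), out.begin());
  return List::create(_["u"] = out, _["energy_initial"] = E0,
                      _["energy_final"] = E);
}
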