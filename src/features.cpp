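#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// FAST-style segment-test corner detector with an oriented BRIEF-style
// 256-bit binary descriptor, over a bilinear image pyramid.  Images are
// numeric matrices (rows = y), intensities on a 0-255 scale.

static const int circle_dx[16] = {0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1};
static const int circle_dy[16] = {-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3};

struct Img {
  std::vector<double> px;
  int w, h;
  double at(int x, int y) const { return px[static_cast<size_t>(x) * h + y]; }
};

static Img from_matrix(const NumericMatrix &m) {
  Img im;
  im.h = m.nrow(); im.w = m.ncol();
  im.px.assign(m.begin(), m.end());
  return im;
}

static Img resize_bilinear(const Img &src, double scale) {
  Img dst;
  dst.w = std::max(8, (int)std::round(src.w / scale));
  dst.h = std::max(8, (int)std::round(src.h / scale));
  dst.px.resize(static_cast<size_t>(dst.w) * dst.h);
  const double sx = (double)src.w / dst.w, sy = (double)src.h / dst.h;
  for (int x = 0; x < dst.w; ++x) {
    double fx = std::min((x + 0.5) * sx - 0.5, src.w - 1.0);
    if (fx < 0) fx = 0;
    int x0 = (int)fx; int x1 = std::min(x0 + 1, src.w - 1);
    double ax = fx - x0;
    for (int y = 0; y < dst.h; ++y) {
      double fy = std::min((y + 0.5) * sy - 0.5, src.h - 1.0);
      if (fy < 0) fy = 0;
      int y0 = (int)fy; int y1 = std::min(y0 + 1, src.h - 1);
      double ay = fy - y0;
      double v = (1 - ax) * ((1 - ay) * src.at(x0, y0) + ay * src.at(x0, y1)) +
                 ax * ((1 - ay) * src.at(x1, y0) + ay * src.at(x1, y1));
      dst.px[static_cast<size_t>(x) * dst.h + y] = v;
    }
  }
  return dst;
}

static Img box_blur5(const Img &src) {
  // separable 5x5 box blur used before descriptor sampling
  Img tmp = src, dst = src;
  for (int y = 0; y < src.h; ++y)
    for (int x = 0; x < src.w; ++x) {
      double s = 0; int n = 0;
      for (int d = -2; d <= 2; ++d) {
        int xx = x + d;
        if (xx >= 0 && xx < src.w) { s += src.at(xx, y); ++n; }
      }
      tmp.px[static_cast<size_t>(x) * src.h + y] = s / n;
    }
  for (int x = 0; x < src.w; ++x)
    for (int y = 0; y < src.h; ++y) {
      double s = 0; int n = 0;
      for (int d = -2; d <= 2; ++d) {
        int yy = y + d;
        if (yy >= 0 && yy < src.h) { s += tmp.at(x, yy); ++n; }
      }
      dst.px[static_cast<size_t>(x) * src.h + y] = s / n;
    }
  return dst;
}

static bool fast_test(const double *px, const int64_t *off, double t,
                      double &score) {
  const double c = *px;
  // high-speed reject: any 9-long arc contains >= 2 of the 4 cardinal
  // circle pixels, so at least 2 must pass the threshold on the same side
  int nb = 0, nd = 0;
  for (int k = 0; k < 16; k += 4) {
    double dv = px[off[k]] - c;
    if (dv > t) ++nb;
    else if (dv < -t) ++nd;
  }
  if (nb < 2 && nd < 2) return false;
  double diff[32];
  for (int i = 0; i < 16; ++i) {
    diff[i] = px[off[i]] - c;
    diff[i + 16] = diff[i];
  }
  // contiguous arc of >=9 pixels all brighter or all darker by > t
  int run_b = 0, run_d = 0;
  bool ok = false;
  for (int i = 0; i < 32 && !ok; ++i) {
    run_b = diff[i] > t ? run_b + 1 : 0;
    run_d = diff[i] < -t ? run_d + 1 : 0;
    if (run_b >= 9 || run_d >= 9) ok = true;
  }
  if (!ok) return false;
  score = 0;
  for (int i = 0; i < 16; ++i) score += std::max(0.0, std::fabs(diff[i]) - t);
  return true;
}

// deterministic BRIEF sampling pattern from a fixed LCG (offsets in [-13,13])
static void brief_pattern(int (&pat)[256][4]) {
  uint64_t s = 0x9E3779B97F4A7C15ULL;
  auto nxt = [&]() {
    s = s * 6364136223846793005ULL + 1442695040888963407ULL;
    return (int)((s >> 33) % 27) - 13;
  };
  for (int i = 0; i < 256; ++i)
    for (int j = 0; j < 4; ++j) pat[i][j] = nxt();
}

struct Kp { double x, y, score, angle; int level; };

// [[Rcpp::export]]
List detect_orb_cpp(NumericMatrix image, int n_features = 1000,
                    double threshold = 20.0, int n_levels = 3,
                    double scale_factor = 1.2) {
  Img base = from_matrix(image);
  std::vector<Kp> kps;
  std::vector<Img> pyr, pyrb;
  double scale = 1.0;
  for (int lv = 0; lv < n_levels; ++lv) {
    Img lvl = lv == 0 ? base : resize_bilinear(base, scale);
    pyr.push_back(lvl);
    pyrb.push_back(box_blur5(lvl));
    const Img &im = pyr[lv];
    const int margin = 17;
    int64_t off[16];
    for (int k = 0; k < 16; ++k)
      off[k] = static_cast<int64_t>(circle_dx[k]) * im.h + circle_dy[k];
    std::vector<double> smap(static_cast<size_t>(im.w) * im.h, 0.0);
    for (int x = margin; x < im.w - margin; ++x) {
      const double *col = &im.px[static_cast<size_t>(x) * im.h];
      for (int y = margin; y < im.h - margin; ++y) {
        double sc;
        if (fast_test(col + y, off, threshold, sc))
          smap[static_cast<size_t>(x) * im.h + y] = sc;
      }
    }
    for (int x = margin; x < im.w - margin; ++x)
      for (int y = margin; y < im.h - margin; ++y) {
        double sc = smap[static_cast<size_t>(x) * im.h + y];
        if (sc <= 0) continue;
        bool mx = true;
        for (int dx = -1; dx <= 1 && mx; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            if (dx == 0 && dy == 0) continue;
            if (smap[static_cast<size_t>(x + dx) * im.h + y + dy] > sc) { mx = false; break; }
          }
        if (!mx) continue;
        Kp kp;
        kp.x = x * scale; kp.y = y * scale;
        kp.score = sc; kp.level = lv;
        kp.angle = 0;
        kps.push_back(kp);
      }
    scale *= scale_factor;
  }
  std::sort(kps.begin(), kps.end(),
            [](const Kp &a, const Kp &b) { return a.score > b.score; });
  if ((int)kps.size() > n_features) kps.resize(n_features);

  static int pat[256][4];
  static bool init = false;
  if (!init) { brief_pattern(pat); init = true; }

  const int n = kps.size();
  NumericVector xs(n), ys(n), scores(n), angles(n), intens(n);
  IntegerVector levels(n);
  IntegerMatrix desc(n, 32);
  double lvscale = 1.0;
  std::vector<double> lvscales(n_levels);
  for (int lv = 0; lv < n_levels; ++lv) { lvscales[lv] = lvscale; lvscale *= scale_factor; }
  for (int i = 0; i < n; ++i) {
    Kp &kp = kps[i];
    double sc = lvscales[kp.level];
    int px = (int)std::round(kp.x / sc), py = (int)std::round(kp.y / sc);
    // orientation by intensity centroid (radius 7 disc), kept points only
    {
      const Img &lvl = pyr[kp.level];
      double m01 = 0, m10 = 0;
      for (int dx = -7; dx <= 7; ++dx)
        for (int dy = -7; dy <= 7; ++dy) {
          if (dx * dx + dy * dy > 49) continue;
          double v = lvl.at(px + dx, py + dy);
          m10 += dx * v; m01 += dy * v;
        }
      kp.angle = std::atan2(m01, m10);
    }
    xs[i] = kp.x; ys[i] = kp.y; scores[i] = kp.score;
    angles[i] = kp.angle; levels[i] = kp.level;
    int xi = std::min(base.w - 1, std::max(0, (int)std::round(kp.x)));
    int yi = std::min(base.h - 1, std::max(0, (int)std::round(kp.y)));
    intens[i] = base.at(xi, yi);
    const Img &im = pyrb[kp.level];
    const double ca = std::cos(kp.angle), sa = std::sin(kp.angle);
    for (int b = 0; b < 32; ++b) {
      int byte = 0;
      for (int bit = 0; bit < 8; ++bit) {
        const int *p = pat[b * 8 + bit];
        int ax = (int)std::round(ca * p[0] - sa * p[1]);
        int ay = (int)std::round(sa * p[0] + ca * p[1]);
        int bx = (int)std::round(ca * p[2] - sa * p[3]);
        int by = (int)std::round(sa * p[2] + ca * p[3]);
        int x1 = std::min(im.w - 1, std::max(0, px + ax));
        int y1 = std::min(im.h - 1, std::max(0, py + ay));
        int x2 = std::min(im.w - 1, std::max(0, px + bx));
        int y2 = std::min(im.h - 1, std::max(0, py + by));
        if (im.at(x1, y1) < im.at(x2, y2)) byte |= (1 << bit);
      }
      desc(i, b) = byte;
    }
  }
  return List::create(_["x"] = xs, _["y"] = ys, _["score"] = scores,
                      _["angle"] = angles, _["level"] = levels,
                      _["intensity"] = intens, _["descriptor"] = desc);
}

static inline int hamming32(const int *a, const int *b, int stride_a, int stride_b) {
  int d = 0;
  for (int k = 0; k < 32; ++k) {
    unsigned int x = (unsigned int)(a[k * stride_a] ^ b[k * stride_b]);
    d += __builtin_popcount(x);
  }
  return d;
}

// For each row of d1, the best and second-best Hamming match in d2,
// optionally restricted to candidates within a window around (cx, cy).
// cx/cy/radius of length 0 disables the spatial gate.
// [[Rcpp::export]]
List hamming_match_cpp(IntegerMatrix d1, IntegerMatrix d2,
                       NumericVector x2, NumericVector y2,
                       NumericVector cx, NumericVector cy,
                       double radius = -1.0) {
  const int n1 = d1.nrow(), n2 = d2.nrow();
  IntegerVector best(n1, NA_INTEGER), bdist(n1, NA_INTEGER), sdist(n1, NA_INTEGER);
  const bool gated = radius > 0 && cx.size() == n1 && x2.size() == n2;
  for (int i = 0; i < n1; ++i) {
    int b1 = 1 << 30, b2 = 1 << 30, bj = -1;
    for (int j = 0; j < n2; ++j) {
      if (gated) {
        if (std::fabs(x2[j] - cx[i]) > radius || std::fabs(y2[j] - cy[i]) > radius)
          continue;
      }
      int d = hamming32(&d1(i, 0), &d2(j, 0), n1, n2);
      if (d < b1) { b2 = b1; b1 = d; bj = j; }
      else if (d < b2) b2 = d;
    }
    if (bj >= 0) {
      best[i] = bj + 1;
      bdist[i] = b1;
      sdist[i] = b2 >= (1 << 30) ? NA_INTEGER : b2;
    }
  }
  return List::create(_["match"] = best, _["dist"] = bdist, _["second"] = sdist);
}

// Mutual-best Hamming matching of two descriptor sets in one pass:
// for each row of d1 the best and second-best in d2, plus the best match
// of every d2 row, so the caller can cross-check without a second scan.
// [[Rcpp::export]]
List mutual_match_cpp(IntegerMatrix d1, IntegerMatrix d2) {
  const int n1 = d1.nrow(), n2 = d2.nrow();
  IntegerVector best(n1, NA_INTEGER), bdist(n1, NA_INTEGER),
      sdist(n1, NA_INTEGER);
  std::vector<int> rbest(n2, -1), rdist(n2, 1 << 30);
  for (int i = 0; i < n1; ++i) {
    int b1 = 1 << 30, b2 = 1 << 30, bj = -1;
    for (int j = 0; j < n2; ++j) {
      int d = hamming32(&d1(i, 0), &d2(j, 0), n1, n2);
      if (d < b1) { b2 = b1; b1 = d; bj = j; }
      else if (d < b2) b2 = d;
      if (d < rdist[j]) { rdist[j] = d; rbest[j] = i; }
    }
    if (bj >= 0) {
      best[i] = bj + 1;
      bdist[i] = b1;
      sdist[i] = b2 >= (1 << 30) ? NA_INTEGER : b2;
    }
  }
  IntegerVector rev(n2);
  for (int j = 0; j < n2; ++j) rev[j] = rbest[j] < 0 ? NA_INTEGER : rbest[j] + 1;
  return List::create(_["match"] = best, _["dist"] = bdist,
                      _["second"] = sdist, _["reverse"] = rev);
}
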