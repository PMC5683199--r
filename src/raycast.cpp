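#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Ray-mesh intersection (Moller-Trumbore, nearest hit) and an iterative
// triangle-unfolding geodesic distance field over a mesh.

// [[Rcpp::export]]
List ray_mesh_cpp(NumericVector orig, NumericMatrix dirs,
                  NumericMatrix V, IntegerMatrix F) {
  const int nr = dirs.nrow(), nf = F.nrow();
  IntegerVector hit(nr, 0);
  NumericVector tout(nr, NA_REAL), uout(nr, NA_REAL), vout(nr, NA_REAL);
  const double eps = 1e-12;
  for (int r = 0; r < nr; ++r) {
    double dx = dirs(r, 0), dy = dirs(r, 1), dz = dirs(r, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int f = 0; f < nf; ++f) {
      int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
      double e1x = V(b, 0) - V(a, 0), e1y = V(b, 1) - V(a, 1), e1z = V(b, 2) - V(a, 2);
      double e2x = V(c, 0) - V(a, 0), e2y = V(c, 1) - V(a, 1), e2z = V(c, 2) - V(a, 2);
      double px = dy * e2z - dz * e2y, py = dz * e2x - dx * e2z, pz = dx * e2y - dy * e2x;
      double det = e1x * px + e1y * py + e1z * pz;
      if (std::fabs(det) < eps) continue;
      double inv = 1.0 / det;
      double tx = orig[0] - V(a, 0), ty = orig[1] - V(a, 1), tz = orig[2] - V(a, 2);
      double u = (tx * px + ty * py + tz * pz) * inv;
      if (u < -1e-9 || u > 1 + 1e-9) continue;
      double qx = ty * e1z - tz * e1y, qy = tz * e1x - tx * e1z, qz = tx * e1y - ty * e1x;
      double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < -1e-9 || u + v > 1 + 1e-9) continue;
      double t = (e2x * qx + e2y * qy + e2z * qz) * inv;
      if (t <= 1e-9 || t >= best) continue;
      best = t;
      hit[r] = f + 1;
      tout[r] = t;
      uout[r] = u;
      vout[r] = v;
    }
  }
  return List::create(_["face"] = hit, _["t"] = tout, _["u"] = uout, _["v"] = vout);
}

// Geodesic distance from seed vertices by repeated triangle relaxation:
// each sweep updates every face vertex from the other two via the planar
// unfolding (fast-marching) update, falling back to the edge (Dijkstra)
// bound; converges to a first-order geodesic approximation.
// [[Rcpp::export]]
NumericVector geodesic_dist_cpp(NumericMatrix V, IntegerMatrix F,
                                IntegerVector seeds, NumericVector seed_dist,
                                int max_sweeps = 300, double tol = 1e-9) {
  const int n = V.nrow(), nf = F.nrow();
  NumericVector d(n, R_PosInf);
  for (int i = 0; i < seeds.size(); ++i) {
    int s = seeds[i] - 1;
    if (s >= 0 && s < n) d[s] = std::min((double)d[s], (double)seed_dist[i]);
  }
  auto elen = [&](int a, int b) {
    double dx = V(a, 0) - V(b, 0), dy = V(a, 1) - V(b, 1), dz = V(a, 2) - V(b, 2);
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  };
  auto update = [&](int c, int a, int b) {
    // distance at c from distances at a, b across triangle (a, b, c)
    double da = d[a], db = d[b];
    double lca = elen(c, a), lcb = elen(c, b);
    double cand = std::min(da + lca, db + lcb);
    if (R_finite(da) && R_finite(db)) {
      double lab = elen(a, b);
      if (lab > 1e-12) {
        // unfold: place a=(0,0), b=(lab,0); c above the axis
        double ax2 = (lca * lca - lcb * lcb + lab * lab) / (2 * lab);
        double h2 = lca * lca - ax2 * ax2;
        if (h2 > 0) {
          double h = std::sqrt(h2);
          // virtual source: intersection consistent with da, db on the axis
          double sx = (da * da - db * db + lab * lab) / (2 * lab);
          double sh2 = da * da - sx * sx;
          if (sh2 >= 0) {
            double sy = -std::sqrt(sh2);  // below the axis (wave from outside)
            double dx = ax2 - sx, dy = h - sy;
            double cand2 = std::sqrt(dx * dx + dy * dy);
            // accept only when the straight segment crosses the a-b edge
            if (sy < -1e-12) {
              double tcross = -sy / (h - sy);
              double xcross = sx + tcross * (ax2 - sx);
              if (xcross >= -1e-9 && xcross <= lab + 1e-9 && cand2 < cand)
                cand = cand2;
            }
          }
        }
      }
    }
    if (cand < d[c]) { d[c] = cand; return true; }
    return false;
  };
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool changed = false;
    for (int f = 0; f < nf; ++f) {
      int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
      if (update(c, a, b)) changed = true;
      if (update(a, b, c)) changed = true;
      if (update(b, c, a)) changed = true;
    }
    for (int f = nf - 1; f >= 0; --f) {
      int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
      if (update(c, a, b)) changed = true;
      if (update(a, b, c)) changed = true;
      if (update(b, c, a)) changed = true;
    }
    if (!changed) break;
  }
  return d;
}
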