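#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <array>
using namespace Rcpp;

// Point-cloud kernels: uniform-grid neighbour search, plane-fit normal
// estimation, voxel-grid downsampling, and a greedy-projection style
// triangulation built from per-point local Delaunay stars.

static inline int64_t cell_key(int ix, int iy, int iz) {
  return (static_cast<int64_t>(ix + 1048576) << 42) |
         (static_cast<int64_t>(iy + 1048576) << 21) |
         static_cast<int64_t>(iz + 1048576);
}

struct Grid {
  double cell;
  std::unordered_map<int64_t, std::vector<int>> cells;
  void build(const NumericMatrix &P, double c) {
    cell = c;
    cells.clear();
    for (int i = 0; i < P.nrow(); ++i) {
      int ix = (int)std::floor(P(i, 0) / cell);
      int iy = (int)std::floor(P(i, 1) / cell);
      int iz = (int)std::floor(P(i, 2) / cell);
      cells[cell_key(ix, iy, iz)].push_back(i);
    }
  }
  // indices within `radius` of point i (excluding i), sorted by distance
  void neighbours(const NumericMatrix &P, int i, double radius, int max_nn,
                  std::vector<int> &out) const {
    out.clear();
    std::vector<std::pair<double, int>> cand;
    const double r2 = radius * radius;
    int cx = (int)std::floor(P(i, 0) / cell);
    int cy = (int)std::floor(P(i, 1) / cell);
    int cz = (int)std::floor(P(i, 2) / cell);
    int span = (int)std::ceil(radius / cell);
    for (int dx = -span; dx <= span; ++dx)
      for (int dy = -span; dy <= span; ++dy)
        for (int dz = -span; dz <= span; ++dz) {
          auto it = cells.find(cell_key(cx + dx, cy + dy, cz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            if (j == i) continue;
            double ddx = P(j, 0) - P(i, 0), ddy = P(j, 1) - P(i, 1),
                   ddz = P(j, 2) - P(i, 2);
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 <= r2) cand.push_back({d2, j});
          }
        }
    std::sort(cand.begin(), cand.end());
    if ((int)cand.size() > max_nn) cand.resize(max_nn);
    for (auto &c : cand) out.push_back(c.second);
  }
};

// smallest-eigenvalue eigenvector of a symmetric 3x3 by Jacobi rotations
static void min_eigvec3(double a[3][3], double v[3]) {
  double q[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  for (int sweep = 0; sweep < 30; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off < 1e-14) break;
    for (int p = 0; p < 2; ++p)
      for (int r = p + 1; r < 3; ++r) {
        if (std::fabs(a[p][r]) < 1e-16) continue;
        double theta = (a[r][r] - a[p][p]) / (2 * a[p][r]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1));
        double c = 1.0 / std::sqrt(t * t + 1), s = t * c;
        for (int k = 0; k < 3; ++k) {
          double akp = a[k][p], akr = a[k][r];
          a[k][p] = c * akp - s * akr;
          a[k][r] = s * akp + c * akr;
        }
        for (int k = 0; k < 3; ++k) {
          double apk = a[p][k], ark = a[r][k];
          a[p][k] = c * apk - s * ark;
          a[r][k] = s * apk + c * ark;
          double qkp = q[k][p], qkr = q[k][r];
          q[k][p] = c * qkp - s * qkr;
          q[k][r] = s * qkp + c * qkr;
        }
      }
  }
  int mi = 0;
  if (a[1][1] < a[mi][mi]) mi = 1;
  if (a[2][2] < a[mi][mi]) mi = 2;
  for (int k = 0; k < 3; ++k) v[k] = q[k][mi];
}

// Per-point unit normals from a plane fit over the k nearest neighbours
// within `radius`, oriented toward the corresponding viewpoint row (a single
// row is recycled).
// [[Rcpp::export]]
NumericMatrix estimate_normals_cpp(NumericMatrix P, NumericMatrix viewpoints,
                                   int k = 20, double radius = 10.0) {
  const int n = P.nrow();
  NumericMatrix N(n, 3);
  Grid g;
  g.build(P, std::max(radius / 2.0, 1e-6));
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    g.neighbours(P, i, radius, k, nb);
    double nx = 0, ny = 0, nz = 1;
    if ((int)nb.size() >= 3) {
      double mx = P(i, 0), my = P(i, 1), mz = P(i, 2);
      for (int j : nb) { mx += P(j, 0); my += P(j, 1); mz += P(j, 2); }
      double m = nb.size() + 1.0;
      mx /= m; my /= m; mz /= m;
      double C[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      auto acc = [&](double x, double y, double z) {
        double dx = x - mx, dy = y - my, dz = z - mz;
        C[0][0] += dx * dx; C[0][1] += dx * dy; C[0][2] += dx * dz;
        C[1][1] += dy * dy; C[1][2] += dy * dz; C[2][2] += dz * dz;
      };
      acc(P(i, 0), P(i, 1), P(i, 2));
      for (int j : nb) acc(P(j, 0), P(j, 1), P(j, 2));
      C[1][0] = C[0][1]; C[2][0] = C[0][2]; C[2][1] = C[1][2];
      double v[3];
      min_eigvec3(C, v);
      nx = v[0]; ny = v[1]; nz = v[2];
    }
    int vrow = viewpoints.nrow() == n ? i : 0;
    double vx = viewpoints(vrow, 0) - P(i, 0), vy = viewpoints(vrow, 1) - P(i, 1),
           vz = viewpoints(vrow, 2) - P(i, 2);
    if (nx * vx + ny * vy + nz * vz < 0) { nx = -nx; ny = -ny; nz = -nz; }
    double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
    N(i, 0) = nx / nn; N(i, 1) = ny / nn; N(i, 2) = nz / nn;
  }
  return N;
}

// Voxel-grid downsample: one centroid per occupied voxel, in first-visit order.
// [[Rcpp::export]]
NumericMatrix voxel_downsample_cpp(NumericMatrix P, double voxel) {
  std::unordered_map<int64_t, int> slot;
  std::vector<double> sx, sy, sz;
  std::vector<int> cnt;
  for (int i = 0; i < P.nrow(); ++i) {
    int ix = (int)std::floor(P(i, 0) / voxel);
    int iy = (int)std::floor(P(i, 1) / voxel);
    int iz = (int)std::floor(P(i, 2) / voxel);
    int64_t key = cell_key(ix, iy, iz);
    auto it = slot.find(key);
    if (it == slot.end()) {
      slot[key] = sx.size();
      sx.push_back(P(i, 0)); sy.push_back(P(i, 1)); sz.push_back(P(i, 2));
      cnt.push_back(1);
    } else {
      int s = it->second;
      sx[s] += P(i, 0); sy[s] += P(i, 1); sz[s] += P(i, 2);
      ++cnt[s];
    }
  }
  NumericMatrix out(sx.size(), 3);
  for (size_t i = 0; i < sx.size(); ++i) {
    out(i, 0) = sx[i] / cnt[i];
    out(i, 1) = sy[i] / cnt[i];
    out(i, 2) = sz[i] / cnt[i];
  }
  return out;
}

// ---- local 2D Delaunay (Bowyer-Watson) on a small projected point set ----

struct Tri { int a, b, c; bool alive; };

static bool in_circumcircle(double ax, double ay, double bx, double by,
                            double cx, double cy, double px, double py) {
  // assumes (a, b, c) counter-clockwise
  double adx = ax - px, ady = ay - py;
  double bdx = bx - px, bdy = by - py;
  double cdx = cx - px, cdy = cy - py;
  double det = (adx * adx + ady * ady) * (bdx * cdy - cdx * bdy) -
               (bdx * bdx + bdy * bdy) * (adx * cdy - cdx * ady) +
               (cdx * cdx + cdy * cdy) * (adx * bdy - bdx * ady);
  return det > 0;
}

static void delaunay2d(const std::vector<double> &x, const std::vector<double> &y,
                       std::vector<Tri> &tris) {
  const int n = x.size();
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  double dmax = std::max(xmax - xmin, ymax - ymin) + 1.0;
  double mx = (xmin + xmax) / 2, my = (ymin + ymax) / 2;
  std::vector<double> px(x), py(y);
  px.push_back(mx - 20 * dmax); py.push_back(my - 10 * dmax);
  px.push_back(mx);             py.push_back(my + 20 * dmax);
  px.push_back(mx + 20 * dmax); py.push_back(my - 10 * dmax);
  tris.clear();
  tris.push_back({n, n + 1, n + 2, true});
  auto ccw = [&](Tri &t) {
    double cr = (px[t.b] - px[t.a]) * (py[t.c] - py[t.a]) -
                (px[t.c] - px[t.a]) * (py[t.b] - py[t.a]);
    if (cr < 0) std::swap(t.b, t.c);
  };
  ccw(tris[0]);
  for (int i = 0; i < n; ++i) {
    std::vector<std::pair<int, int>> edges;
    for (auto &t : tris) {
      if (!t.alive) continue;
      if (in_circumcircle(px[t.a], py[t.a], px[t.b], py[t.b],
                          px[t.c], py[t.c], px[i], py[i])) {
        t.alive = false;
        edges.push_back({t.a, t.b});
        edges.push_back({t.b, t.c});
        edges.push_back({t.c, t.a});
      }
    }
    // boundary edges of the cavity appear exactly once (in either direction)
    for (size_t e = 0; e < edges.size(); ++e) {
      bool shared = false;
      for (size_t f = 0; f < edges.size(); ++f) {
        if (e == f) continue;
        if ((edges[e].first == edges[f].second && edges[e].second == edges[f].first) ||
            (edges[e].first == edges[f].first && edges[e].second == edges[f].second)) {
          shared = true;
          break;
        }
      }
      if (shared) continue;
      Tri t{edges[e].first, edges[e].second, i, true};
      ccw(t);
      tris.push_back(t);
    }
  }
}

// Greedy-projection style surface triangulation: every point's neighbourhood
// is projected onto its tangent plane and locally Delaunay-triangulated; the
// star of the point contributes candidate triangles, kept when at least
// `min_star` of their vertices agree.  Triangles are oriented along the
// supplied per-point normals.
// [[Rcpp::export]]
IntegerMatrix greedy_triangulate_cpp(NumericMatrix P, NumericMatrix N,
                                     double radius, int max_nn = 16,
                                     int min_star = 2) {
  const int n = P.nrow();
  Grid g;
  g.build(P, std::max(radius / 2.0, 1e-9));
  std::unordered_map<uint64_t, int> counts;
  std::unordered_map<uint64_t, std::array<int, 3>> order;
  std::vector<int> nb;
  std::vector<double> lx, ly;
  std::vector<Tri> tris;
  for (int i = 0; i < n; ++i) {
    g.neighbours(P, i, radius, max_nn, nb);
    if ((int)nb.size() < 2) continue;
    // tangent basis at i
    double nx = N(i, 0), ny = N(i, 1), nz = N(i, 2);
    double ex = 0, ey = 0, ez = 0;
    if (std::fabs(nx) <= std::fabs(ny) && std::fabs(nx) <= std::fabs(nz)) ex = 1;
    else if (std::fabs(ny) <= std::fabs(nz)) ey = 1;
    else ez = 1;
    double ux = ny * ez - nz * ey, uy = nz * ex - nx * ez, uz = nx * ey - ny * ex;
    double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    if (un < 1e-12) { ux = 1; uy = 0; uz = 0; un = 1; }
    ux /= un; uy /= un; uz /= un;
    double vx = ny * uz - nz * uy, vy = nz * ux - nx * uz, vz = nx * uy - ny * ux;
    std::vector<int> local;
    local.push_back(i);
    for (int j : nb) local.push_back(j);
    lx.assign(local.size(), 0.0);
    ly.assign(local.size(), 0.0);
    // deterministic per-point jitter breaks exact cocircularity (regular
    // grids); keyed to the global id so all stars agree
    auto jit = [&](int gid, int axis) {
      uint32_t hsh = (uint32_t)(gid * 2654435761u + axis * 40503u);
      hsh ^= hsh >> 13; hsh *= 2246822519u; hsh ^= hsh >> 16;
      return ((hsh & 0xffff) / 65535.0 - 0.5) * 1e-5 * radius;
    };
    for (size_t m = 1; m < local.size(); ++m) {
      double dx = P(local[m], 0) - P(i, 0), dy = P(local[m], 1) - P(i, 1),
             dz = P(local[m], 2) - P(i, 2);
      lx[m] = dx * ux + dy * uy + dz * uz + jit(local[m], 0);
      ly[m] = dx * vx + dy * vy + dz * vz + jit(local[m], 1);
    }
    lx[0] += jit(i, 0);
    ly[0] += jit(i, 1);
    delaunay2d(lx, ly, tris);
    const int nl = local.size();
    for (auto &t : tris) {
      if (!t.alive) continue;
      if (t.a >= nl || t.b >= nl || t.c >= nl) continue;
      if (t.a != 0 && t.b != 0 && t.c != 0) continue;  // star of i only
      int gi[3] = {local[t.a], local[t.b], local[t.c]};
      int s0 = gi[0], s1 = gi[1], s2 = gi[2];
      if (s0 > s1) std::swap(s0, s1);
      if (s1 > s2) std::swap(s1, s2);
      if (s0 > s1) std::swap(s0, s1);
      uint64_t key = (static_cast<uint64_t>(s0) << 42) |
                     (static_cast<uint64_t>(s1) << 21) | s2;
      auto it = counts.find(key);
      if (it == counts.end()) {
        counts[key] = 1;
        order[key] = {gi[0], gi[1], gi[2]};
      } else {
        ++it->second;
      }
    }
  }
  std::vector<std::array<int, 3>> keep;
  for (auto &kv : counts) {
    if (kv.second < min_star) continue;
    auto tr = order[kv.first];
    // degenerate-area guard and orientation along mean vertex normal
    double ax = P(tr[1], 0) - P(tr[0], 0), ay = P(tr[1], 1) - P(tr[0], 1),
           az = P(tr[1], 2) - P(tr[0], 2);
    double bx = P(tr[2], 0) - P(tr[0], 0), by = P(tr[2], 1) - P(tr[0], 1),
           bz = P(tr[2], 2) - P(tr[0], 2);
    double cxn = ay * bz - az * by, cyn = az * bx - ax * bz, czn = ax * by - ay * bx;
    double area2 = std::sqrt(cxn * cxn + cyn * cyn + czn * czn);
    if (area2 < 1e-12) continue;
    double mnx = N(tr[0], 0) + N(tr[1], 0) + N(tr[2], 0);
    double mny = N(tr[0], 1) + N(tr[1], 1) + N(tr[2], 1);
    double mnz = N(tr[0], 2) + N(tr[1], 2) + N(tr[2], 2);
    if (cxn * mnx + cyn * mny + czn * mnz < 0) std::swap(tr[1], tr[2]);
    keep.push_back(tr);
  }
  std::sort(keep.begin(), keep.end());
  IntegerMatrix F(keep.size(), 3);
  for (size_t i = 0; i < keep.size(); ++i) {
    F(i, 0) = keep[i][0] + 1;
    F(i, 1) = keep[i][1] + 1;
    F(i, 2) = keep[i][2] + 1;
  }
  return F;
}
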