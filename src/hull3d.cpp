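// Incremental 3D convex hull (quickhull-style point insertion) used for the
// convex-hull effective cluster radius. Returns the hull volume; NA for
// fewer than 4 points or a degenerate (collinear/coplanar) set.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Face {
  int a, b, c;
  bool alive;
};

static inline double orient(const double *p, int ia, int ib, int ic, int id) {
  // 6 * signed volume of tetra (a, b, c, d); positive if d is on the
  // normal side of the (a,b,c) plane (right-hand rule)
  double bx = p[3 * ib] - p[3 * ia], by = p[3 * ib + 1] - p[3 * ia + 1],
         bz = p[3 * ib + 2] - p[3 * ia + 2];
  double cx = p[3 * ic] - p[3 * ia], cy = p[3 * ic + 1] - p[3 * ia + 1],
         cz = p[3 * ic + 2] - p[3 * ia + 2];
  double dx = p[3 * id] - p[3 * ia], dy = p[3 * id + 1] - p[3 * ia + 1],
         dz = p[3 * id + 2] - p[3 * ia + 2];
  return dx * (by * cz - bz * cy) + dy * (bz * cx - bx * cz) +
         dz * (bx * cy - by * cx);
}

// [[Rcpp::export]]
double cpp_hull_volume(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return NA_REAL;
  std::vector<double> p(3 * n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    p[3 * i] = pts(i, 0);
    p[3 * i + 1] = pts(i, 1);
    p[3 * i + 2] = pts(i, 2);
  }
  // bounding-box scale for tolerances
  for (int a = 0; a < 3; ++a) {
    double lo = p[a], hi = p[a];
    for (int i = 1; i < n; ++i) {
      double v = p[3 * i + a];
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    scale = std::max(scale, hi - lo);
  }
  if (scale <= 0.0) return NA_REAL;
  const double eps = 1e-10 * scale * scale * scale;

  // initial tetrahedron: extreme point pair, then max area, then max volume
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double dx = p[3 * i] - p[0], dy = p[3 * i + 1] - p[1],
           dz = p[3 * i + 2] - p[2];
    double d = dx * dx + dy * dy + dz * dz;
    if (d > best) { best = d; i1 = i; }
  }
  if (best <= 1e-20 * scale * scale) return NA_REAL;
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double ux = p[3 * i1] - p[3 * i0], uy = p[3 * i1 + 1] - p[3 * i0 + 1],
           uz = p[3 * i1 + 2] - p[3 * i0 + 2];
    double vx = p[3 * i] - p[3 * i0], vy = p[3 * i + 1] - p[3 * i0 + 1],
           vz = p[3 * i + 2] - p[3 * i0 + 2];
    double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz,
           cz = ux * vy - uy * vx;
    double a2 = cx * cx + cy * cy + cz * cz;
    if (a2 > best) { best = a2; i2 = i; }
  }
  if (i2 < 0 || best <= 1e-20 * scale * scale * scale * scale) return NA_REAL;
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double v = std::fabs(orient(p.data(), i0, i1, i2, i));
    if (v > best) { best = v; i3 = i; }
  }
  if (i3 < 0 || best <= eps) return NA_REAL;  // coplanar

  std::vector<Face> faces;
  faces.reserve(256);
  // orient each face so the remaining tetra vertex is behind (negative side)
  auto add_oriented = [&](int a, int b, int c, int opp) {
    if (orient(p.data(), a, b, c, opp) > 0) std::swap(b, c);
    faces.push_back({a, b, c, true});
  };
  add_oriented(i0, i1, i2, i3);
  add_oriented(i0, i1, i3, i2);
  add_oriented(i0, i2, i3, i1);
  add_oriented(i1, i2, i3, i0);

  std::vector<int> visible;
  std::vector<std::pair<int, int> > horizon;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    visible.clear();
    for (int f = 0; f < (int)faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (orient(p.data(), faces[f].a, faces[f].b, faces[f].c, i) > eps)
        visible.push_back(f);
    }
    if (visible.empty()) continue;
    // horizon: directed edges of visible faces whose reverse is not among
    // the visible set's edges
    horizon.clear();
    for (size_t vi = 0; vi < visible.size(); ++vi) {
      const Face &f = faces[visible[vi]];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int k = 0; k < 3; ++k) {
        bool shared = false;
        for (size_t vj = 0; vj < visible.size() && !shared; ++vj) {
          if (vj == vi) continue;
          const Face &g = faces[visible[vj]];
          int h[3][2] = {{g.a, g.b}, {g.b, g.c}, {g.c, g.a}};
          for (int m = 0; m < 3; ++m)
            if (h[m][0] == e[k][1] && h[m][1] == e[k][0]) { shared = true; break; }
        }
        if (!shared) horizon.push_back(std::make_pair(e[k][0], e[k][1]));
      }
    }
    for (size_t vi = 0; vi < visible.size(); ++vi)
      faces[visible[vi]].alive = false;
    for (size_t h = 0; h < horizon.size(); ++h)
      faces.push_back({horizon[h].first, horizon[h].second, i, true});
  }

  // interior reference point: centroid of initial tetra
  double q[3];
  for (int a = 0; a < 3; ++a)
    q[a] = 0.25 * (p[3 * i0 + a] + p[3 * i1 + a] + p[3 * i2 + a] +
                   p[3 * i3 + a]);
  double vol6 = 0.0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    const Face &fc = faces[f];
    double ax = p[3 * fc.a] - q[0], ay = p[3 * fc.a + 1] - q[1],
           az = p[3 * fc.a + 2] - q[2];
    double bx = p[3 * fc.b] - q[0], by = p[3 * fc.b + 1] - q[1],
           bz = p[3 * fc.b + 2] - q[2];
    double cx = p[3 * fc.c] - q[0], cy = p[3 * fc.c + 1] - q[1],
           cz = p[3 * fc.c + 2] - q[2];
    vol6 += ax * (by * cz - bz * cy) + ay * (bz * cx - bx * cz) +
            az * (bx * cy - by * cx);
  }
  return std::fabs(vol6) / 6.0;
}
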