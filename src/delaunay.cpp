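#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Incremental Bowyer-Watson Delaunay triangulation of a planar point set.
// Intended for quasi-uniform point clouds (jittered lattices plus boundary
// rings); cocircular degeneracies are broken upstream by a tiny deterministic
// radial perturbation of boundary nodes.

namespace {

struct Tri {
  int a, b, c;
  bool alive;
};

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// p strictly inside circumcircle of CCW triangle (a,b,c)?
inline bool in_circumcircle(double ax, double ay, double bx, double by,
                            double cx, double cy, double px, double py) {
  const double adx = ax - px, ady = ay - py;
  const double bdx = bx - px, bdy = by - py;
  const double cdx = cx - px, cdy = cy - py;
  const double ad = adx * adx + ady * ady;
  const double bd = bdx * bdx + bdy * bdy;
  const double cd = cdx * cdx + cdy * cdy;
  const double det = adx * (bdy * cd - bd * cdy)
                   - ady * (bdx * cd - bd * cdx)
                   + ad * (bdx * cdy - bdy * cdx);
  return det > 0.0;
}

} // namespace

// [[Rcpp::export(name = ".delaunay_cpp")]]
IntegerMatrix delaunay_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 3) stop("need at least 3 points");

  std::vector<double> x(n + 3), y(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    x[i] = pts(i, 0);
    y[i] = pts(i, 1);
    if (!R_finite(x[i]) || !R_finite(y[i])) stop("non-finite point coordinates");
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }

  // enclosing super-triangle, far enough that its circumcircles cover the set
  const double dx = xmax - xmin, dy = ymax - ymin;
  const double dmax = std::max(dx, dy) + 1.0;
  const double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  x[n]     = cx - 30.0 * dmax; y[n]     = cy - 10.0 * dmax;
  x[n + 1] = cx + 30.0 * dmax; y[n + 1] = cy - 10.0 * dmax;
  x[n + 2] = cx;               y[n + 2] = cy + 30.0 * dmax;

  std::vector<Tri> tris;
  tris.reserve(4 * n);
  {
    Tri t; t.a = n; t.b = n + 1; t.c = n + 2; t.alive = true;
    if (orient2d(x[t.a], y[t.a], x[t.b], y[t.b], x[t.c], y[t.c]) < 0)
      std::swap(t.b, t.c);
    tris.push_back(t);
  }

  std::vector<int> bad;
  std::map<std::pair<int, int>, int> edge_count;
  int n_dead = 0;

  for (int p = 0; p < n; ++p) {
    if (n_dead > (int)tris.size() / 2) {
      std::vector<Tri> keep;
      keep.reserve(tris.size() - n_dead);
      for (const Tri &T : tris)
        if (T.alive) keep.push_back(T);
      tris.swap(keep);
      n_dead = 0;
    }
    bad.clear();
    for (int t = 0; t < (int)tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const Tri &T = tris[t];
      if (in_circumcircle(x[T.a], y[T.a], x[T.b], y[T.b],
                          x[T.c], y[T.c], x[p], y[p]))
        bad.push_back(t);
    }
    if (bad.empty()) {
      // p lies on/outside every circumcircle (degenerate); assign it to the
      // triangle that contains it so the triangulation stays a partition
      for (int t = 0; t < (int)tris.size(); ++t) {
        if (!tris[t].alive) continue;
        const Tri &T = tris[t];
        if (orient2d(x[T.a], y[T.a], x[T.b], y[T.b], x[p], y[p]) >= 0 &&
            orient2d(x[T.b], y[T.b], x[T.c], y[T.c], x[p], y[p]) >= 0 &&
            orient2d(x[T.c], y[T.c], x[T.a], y[T.a], x[p], y[p]) >= 0) {
          bad.push_back(t);
          break;
        }
      }
      if (bad.empty()) stop("point insertion failed (degenerate input)");
    }

    // boundary polygon of the cavity = edges appearing exactly once
    edge_count.clear();
    for (int t : bad) {
      const Tri &T = tris[t];
      const int e[3][2] = { {T.a, T.b}, {T.b, T.c}, {T.c, T.a} };
      for (int k = 0; k < 3; ++k) {
        int u = e[k][0], v = e[k][1];
        std::pair<int, int> key = u < v ? std::make_pair(u, v)
                                        : std::make_pair(v, u);
        edge_count[key]++;
      }
      tris[t].alive = false;
      ++n_dead;
    }
    for (int t : bad) {
      // re-walk edges in orientation order so new triangles come out CCW
      const Tri &T = tris[t];
      const int e[3][2] = { {T.a, T.b}, {T.b, T.c}, {T.c, T.a} };
      for (int k = 0; k < 3; ++k) {
        int u = e[k][0], v = e[k][1];
        std::pair<int, int> key = u < v ? std::make_pair(u, v)
                                        : std::make_pair(v, u);
        if (edge_count[key] == 1) {
          Tri nt; nt.a = u; nt.b = v; nt.c = p; nt.alive = true;
          if (orient2d(x[u], y[u], x[v], y[v], x[p], y[p]) < 0)
            std::swap(nt.a, nt.b);
          tris.push_back(nt);
        }
      }
    }
  }

  int m = 0;
  for (const Tri &T : tris)
    if (T.alive && T.a < n && T.b < n && T.c < n) ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (const Tri &T : tris) {
    if (!(T.alive && T.a < n && T.b < n && T.c < n)) continue;
    out(r, 0) = T.a + 1;
    out(r, 1) = T.b + 1;
    out(r, 2) = T.c + 1;
    ++r;
  }
  return out;
}
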