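#include <Rcpp.h>
#include <vector>
#include <utility>
#include <cmath>

using namespace Rcpp;

// Incremental (Bowyer-Watson) Delaunay triangulation of a planar point set.
// The in-circumcircle test uses a cached circumcenter/radius with a
// long-double determinant fallback near ties, which stays reliable once
// callers have broken exact cocircularity (the R side perturbs inputs by
// ~1e-9 um before triangulating).

namespace {

struct Tri {
  int a, b, c;
  double cx, cy, r2;  // circumcircle
  bool alive;
};

inline long double orient2d(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (long double)(bx - ax) * (long double)(cy - ay) -
         (long double)(by - ay) * (long double)(cx - ax);
}

// > 0 iff p lies inside the circumcircle of the CCW triangle (a, b, c)
inline long double incircle_det(double ax, double ay, double bx, double by,
                                double cx, double cy, double px, double py) {
  long double adx = ax - px, ady = ay - py;
  long double bdx = bx - px, bdy = by - py;
  long double cdx = cx - px, cdy = cy - py;
  long double ad = adx * adx + ady * ady;
  long double bd = bdx * bdx + bdy * bdy;
  long double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy) - ady * (bdx * cd - bd * cdx) +
         ad * (bdx * cdy - bdy * cdx);
}

}  // namespace

// [[Rcpp::export(name = ".delaunay_cpp")]]
IntegerMatrix delaunay_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) stop("triangulation needs at least 3 points");

  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double dmax = std::max(xmax - xmin, ymax - ymin);
  if (dmax <= 0) dmax = 1.0;
  double cx0 = 0.5 * (xmin + xmax), cy0 = 0.5 * (ymin + ymax);

  std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
  // super-triangle vertices at indices n, n+1, n+2
  px.push_back(cx0 - 30.0 * dmax); py.push_back(cy0 - 10.0 * dmax);
  px.push_back(cx0 + 30.0 * dmax); py.push_back(cy0 - 10.0 * dmax);
  px.push_back(cx0);               py.push_back(cy0 + 30.0 * dmax);

  std::vector<Tri> tris;
  tris.reserve(6 * n);

  struct Maker {
    const std::vector<double> &px, &py;
    Maker(const std::vector<double> &px_, const std::vector<double> &py_)
        : px(px_), py(py_) {}
    Tri make(int a, int b, int c) const {
      if (orient2d(px[a], py[a], px[b], py[b], px[c], py[c]) < 0)
        std::swap(b, c);
      double ax = px[a], ay = py[a];
      double bxr = px[b] - ax, byr = py[b] - ay;
      double cxr = px[c] - ax, cyr = py[c] - ay;
      double d = 2.0 * (bxr * cyr - byr * cxr);
      double b2 = bxr * bxr + byr * byr, c2 = cxr * cxr + cyr * cyr;
      double ux = (cyr * b2 - byr * c2) / d;
      double uy = (bxr * c2 - cxr * b2) / d;
      Tri t;
      t.a = a; t.b = b; t.c = c;
      t.cx = ax + ux; t.cy = ay + uy;
      t.r2 = ux * ux + uy * uy;
      t.alive = true;
      return t;
    }
  } maker(px, py);

  tris.push_back(maker.make(n, n + 1, n + 2));

  typedef std::pair<int, int> Edge;
  std::vector<std::pair<Edge, int> > edges;  // cavity edges with counts
  std::vector<int> dead;

  for (int i = 0; i < n; ++i) {
    edges.clear();
    dead.clear();
    const double pxi = px[i], pyi = py[i];
    for (size_t t = 0; t < tris.size(); ++t) {
      Tri &tr = tris[t];
      if (!tr.alive) continue;
      double dx = pxi - tr.cx, dy = pyi - tr.cy;
      double d2 = dx * dx + dy * dy;
      bool inside;
      double tol = 1e-9 * tr.r2;
      if (d2 < tr.r2 - tol) {
        inside = true;
      } else if (d2 > tr.r2 + tol) {
        inside = false;
      } else {
        inside = incircle_det(px[tr.a], py[tr.a], px[tr.b], py[tr.b],
                              px[tr.c], py[tr.c], pxi, pyi) > 0;
      }
      if (!inside) continue;
      tr.alive = false;
      dead.push_back((int)t);
      const int e[3][2] = {{tr.a, tr.b}, {tr.b, tr.c}, {tr.c, tr.a}};
      for (int k = 0; k < 3; ++k) {
        Edge key(std::min(e[k][0], e[k][1]), std::max(e[k][0], e[k][1]));
        bool found = false;
        for (size_t q = 0; q < edges.size(); ++q) {
          if (edges[q].first == key) { edges[q].second += 1; found = true; break; }
        }
        if (!found) edges.push_back(std::make_pair(key, 1));
      }
    }
    if (dead.empty()) stop("degenerate input: duplicate point at index %d", i + 1);
    size_t reuse = 0;
    for (size_t q = 0; q < edges.size(); ++q) {
      if (edges[q].second != 1) continue;
      Tri t = maker.make(edges[q].first.first, edges[q].first.second, i);
      if (reuse < dead.size()) {
        tris[dead[reuse++]] = t;
      } else {
        tris.push_back(t);
      }
    }
  }

  int m = 0;
  for (size_t t = 0; t < tris.size(); ++t)
    if (tris[t].alive && tris[t].a < n && tris[t].b < n && tris[t].c < n) ++m;
  if (m == 0) stop("degenerate input: all points are collinear");

  IntegerMatrix out(m, 3);
  int r = 0;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (!tris[t].alive) continue;
    if (tris[t].a >= n || tris[t].b >= n || tris[t].c >= n) continue;
    out(r, 0) = tris[t].a + 1;
    out(r, 1) = tris[t].b + 1;
    out(r, 2) = tris[t].c + 1;
    ++r;
  }
  return out;
}
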