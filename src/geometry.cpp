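#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Closed polygons are passed as coordinate vectors WITHOUT a repeated final
// vertex; edge i joins vertex i to vertex (i+1) mod n throughout.

static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

// Proper / improper intersection of segments p1-p2 and p3-p4.
// Returns true and fills t (parameter along p1-p2) when the open interiors
// cross; endpoint touching is treated as crossing (degenerate inputs are
// rejected upstream by retry, so this only needs to be consistent).
static bool seg_intersect_t(double x1, double y1, double x2, double y2,
                            double x3, double y3, double x4, double y4,
                            double &t, double &u) {
  const double rx = x2 - x1, ry = y2 - y1;
  const double sx = x4 - x3, sy = y4 - y3;
  const double denom = cross2(rx, ry, sx, sy);
  if (denom == 0.0) return false;  // parallel or collinear: no unique point
  const double qpx = x3 - x1, qpy = y3 - y1;
  t = cross2(qpx, qpy, sx, sy) / denom;
  u = cross2(qpx, qpy, rx, ry) / denom;
  return (t > 0.0 && t < 1.0 && u > 0.0 && u < 1.0);
}

// [[Rcpp::export]]
bool cpp_is_simple(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) return false;
  for (int i = 0; i < n; ++i) {
    const int i2 = (i + 1) % n;
    // zero-length segment check
    if (x[i] == x[i2] && y[i] == y[i2]) return false;
    for (int j = i + 1; j < n; ++j) {
      const int j2 = (j + 1) % n;
      // skip adjacent edges (share a vertex)
      if (j == i || j2 == i || j == i2) continue;
      double t, u;
      if (seg_intersect_t(x[i], y[i], x[i2], y[i2],
                          x[j], y[j], x[j2], y[j2], t, u))
        return false;
    }
  }
  return true;
}

// Even-odd ray casting.
static bool point_in_poly1(double px, double py,
                           const NumericVector &x, const NumericVector &y) {
  const int n = x.size();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if (((y[i] > py) != (y[j] > py)) &&
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]))
      inside = !inside;
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector cpp_point_in_poly(NumericVector px, NumericVector py,
                                NumericVector x, NumericVector y) {
  const int m = px.size();
  LogicalVector out(m);
  for (int k = 0; k < m; ++k) out[k] = point_in_poly1(px[k], py[k], x, y);
  return out;
}

// All crossings between edges of polygon A and edges of polygon B.
// Returns a matrix with columns (edge_a (1-based), t_a, edge_b (1-based), t_b).
// [[Rcpp::export]]
NumericMatrix cpp_poly_edge_intersections(NumericVector xa, NumericVector ya,
                                          NumericVector xb, NumericVector yb) {
  const int n = xa.size(), m = xb.size();
  std::vector<double> rows;
  for (int i = 0; i < n; ++i) {
    const int i2 = (i + 1) % n;
    for (int j = 0; j < m; ++j) {
      const int j2 = (j + 1) % m;
      double t, u;
      if (seg_intersect_t(xa[i], ya[i], xa[i2], ya[i2],
                          xb[j], yb[j], xb[j2], yb[j2], t, u)) {
        rows.push_back(i + 1); rows.push_back(t);
        rows.push_back(j + 1); rows.push_back(u);
      }
    }
  }
  const int k = rows.size() / 4;
  NumericMatrix out(k, 4);
  for (int r = 0; r < k; ++r)
    for (int c = 0; c < 4; ++c) out(r, c) = rows[4 * r + c];
  return out;
}

// Area of intersection of two simple polygons via boundary integration:
// the boundary of A∩B consists of the sub-segments of ∂A inside B and of
// ∂B inside A, split at edge crossings; each directed sub-segment (p,q)
// contributes cross(p,q)/2 to the shoelace integral. Orientation-agnostic:
// returns |area|. Robust for shapes in general position (the generator
// retries on degeneracy).
static double half_intersection(const NumericVector &xa, const NumericVector &ya,
                                const NumericVector &xb, const NumericVector &yb) {
  const int n = xa.size(), m = xb.size();
  double acc = 0.0;
  // per-edge bounding boxes of B for cheap rejection
  std::vector<double> bx0(m), bx1(m), by0(m), by1(m);
  for (int j = 0; j < m; ++j) {
    const int j2 = (j + 1) % m;
    bx0[j] = std::min(xb[j], xb[j2]); bx1[j] = std::max(xb[j], xb[j2]);
    by0[j] = std::min(yb[j], yb[j2]); by1[j] = std::max(yb[j], yb[j2]);
  }
  // walk ∂A once, maintaining the inside-B flag by parity: it can only flip
  // at a recorded crossing, so point-in-polygon is evaluated a single time
  std::vector<double> ts;
  ts.reserve(8);
  bool inside = false, have_status = false;
  for (int i = 0; i < n; ++i) {
    const int i2 = (i + 1) % n;
    const double ex0 = std::min(xa[i], xa[i2]), ex1 = std::max(xa[i], xa[i2]);
    const double ey0 = std::min(ya[i], ya[i2]), ey1 = std::max(ya[i], ya[i2]);
    ts.clear();
    for (int j = 0; j < m; ++j) {
      if (bx1[j] < ex0 || bx0[j] > ex1 || by1[j] < ey0 || by0[j] > ey1)
        continue;
      const int j2 = (j + 1) % m;
      double t, u;
      if (seg_intersect_t(xa[i], ya[i], xa[i2], ya[i2],
                          xb[j], yb[j], xb[j2], yb[j2], t, u))
        ts.push_back(t);
    }
    ts.push_back(1.0);
    std::sort(ts.begin(), ts.end());
    double t0 = 0.0;
    for (size_t k = 0; k < ts.size(); ++k) {
      const double t1 = ts[k];
      if (t1 > t0) {
        if (!have_status) {
          const double tm = 0.5 * (t0 + t1);
          inside = point_in_poly1(xa[i] + tm * (xa[i2] - xa[i]),
                                  ya[i] + tm * (ya[i2] - ya[i]), xb, yb);
          have_status = true;
        }
        if (inside) {
          const double p0x = xa[i] + t0 * (xa[i2] - xa[i]);
          const double p0y = ya[i] + t0 * (ya[i2] - ya[i]);
          const double p1x = (t1 == 1.0) ? xa[i2] : xa[i] + t1 * (xa[i2] - xa[i]);
          const double p1y = (t1 == 1.0) ? ya[i2] : ya[i] + t1 * (ya[i2] - ya[i]);
          acc += 0.5 * cross2(p0x, p0y, p1x, p1y);
        }
      }
      if (t1 < 1.0 && have_status) inside = !inside;  // passed a crossing
      t0 = t1;
    }
  }
  return acc;
}

// [[Rcpp::export]]
double cpp_intersection_area(NumericVector xa, NumericVector ya,
                             NumericVector xb, NumericVector yb) {
  // orient both counterclockwise so contributions add with one sign
  double sa = 0.0, sb = 0.0;
  const int n = xa.size(), m = xb.size();
  for (int i = 0; i < n; ++i) {
    const int i2 = (i + 1) % n;
    sa += cross2(xa[i], ya[i], xa[i2], ya[i2]);
  }
  for (int j = 0; j < m; ++j) {
    const int j2 = (j + 1) % m;
    sb += cross2(xb[j], yb[j], xb[j2], yb[j2]);
  }
  NumericVector xa2 = clone(xa), ya2 = clone(ya), xb2 = clone(xb), yb2 = clone(yb);
  if (sa < 0) { std::reverse(xa2.begin(), xa2.end()); std::reverse(ya2.begin(), ya2.end()); }
  if (sb < 0) { std::reverse(xb2.begin(), xb2.end()); std::reverse(yb2.begin(), yb2.end()); }
  const double area = half_intersection(xa2, ya2, xb2, yb2) +
                      half_intersection(xb2, yb2, xa2, ya2);
  return area < 0.0 ? 0.0 : area;
}

// Directed Hausdorff with the early-break scan: a source point whose running
// minimum drops below the current maximum cannot raise the maximum, so its
// inner loop is abandoned.
static double directed_hausdorff(const NumericVector &xa, const NumericVector &ya,
                                 const NumericVector &xb, const NumericVector &yb) {
  const int n = xa.size(), m = xb.size();
  double cmax = 0.0;
  int jwarm = 0;  // consecutive perimeter points have nearby nearest neighbors
  for (int i = 0; i < n; ++i) {
    double cmin = R_PosInf;
    int jbest = jwarm;
    {  // warm start: usually already below cmax, triggering the early break
      const double dx = xa[i] - xb[jwarm], dy = ya[i] - yb[jwarm];
      cmin = dx * dx + dy * dy;
    }
    if (cmin > cmax) {
      for (int j = 0; j < m; ++j) {
        const double dx = xa[i] - xb[j], dy = ya[i] - yb[j];
        const double d = dx * dx + dy * dy;
        if (d < cmin) {
          cmin = d;
          jbest = j;
          if (cmin <= cmax) break;
        }
      }
    }
    jwarm = jbest;
    if (cmin > cmax) cmax = cmin;
  }
  return std::sqrt(cmax);
}

// [[Rcpp::export]]
double cpp_hausdorff(NumericVector xa, NumericVector ya,
                     NumericVector xb, NumericVector yb) {
  return std::max(directed_hausdorff(xa, ya, xb, yb),
                  directed_hausdorff(xb, yb, xa, ya));
}

// Minimum distance from each query point to the edges of each pad.
// pad: 1-based pad index of edge i (edge i joins vertex i and i+1 mod n).
// Returns a (#points x npads) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_pad_min_dists(NumericVector px, NumericVector py,
                                NumericVector x, NumericVector y,
                                IntegerVector pad, int npads) {
  const int q = px.size(), n = x.size();
  NumericMatrix out(q, npads);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int k = 0; k < q; ++k) {
    for (int i = 0; i < n; ++i) {
      const int i2 = (i + 1) % n;
      const double ex = x[i2] - x[i], ey = y[i2] - y[i];
      const double wx = px[k] - x[i], wy = py[k] - y[i];
      const double len2 = ex * ex + ey * ey;
      double t = len2 > 0.0 ? (wx * ex + wy * ey) / len2 : 0.0;
      if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      const double dx = wx - t * ex, dy = wy - t * ey;
      const double d = dx * dx + dy * dy;
      const int p = pad[i] - 1;
      if (d < out(k, p)) out(k, p) = d;
    }
  }
  for (int k = 0; k < q; ++k)
    for (int p = 0; p < npads; ++p) out(k, p) = std::sqrt(out(k, p));
  return out;
}
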