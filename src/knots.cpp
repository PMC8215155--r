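// KMT chain reduction and planar crossing enumeration for knot typing.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline void vsub(const double *a, const double *b, double *o) {
  for (int d = 0; d < 3; ++d) o[d] = a[d] - b[d];
}
static inline double vdot(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void vcross(const double *a, const double *b, double *o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}

// 2D helpers on a chosen projection plane
static bool seg_seg_2d(double ax, double ay, double bx, double by, double cx,
                       double cy, double dx, double dy) {
  double r0 = bx - ax, r1 = by - ay, s0 = dx - cx, s1 = dy - cy;
  double den = r0 * s1 - r1 * s0;
  double qp0 = cx - ax, qp1 = cy - ay;
  const double tol = 1e-12;
  if (std::fabs(den) < tol) {
    // parallel: overlap iff collinear and ranges overlap
    if (std::fabs(qp0 * r1 - qp1 * r0) > 1e-9) return false;
    double rr = r0 * r0 + r1 * r1;
    if (rr < tol) return false;
    double t0 = (qp0 * r0 + qp1 * r1) / rr;
    double t1 = t0 + (s0 * r0 + s1 * r1) / rr;
    if (t0 > t1) std::swap(t0, t1);
    return t1 >= -1e-9 && t0 <= 1 + 1e-9;
  }
  double t = (qp0 * s1 - qp1 * s0) / den;
  double u = (qp0 * r1 - qp1 * r0) / den;
  return t >= -1e-9 && t <= 1 + 1e-9 && u >= -1e-9 && u <= 1 + 1e-9;
}

static bool point_in_tri_2d(double px, double py, double ax, double ay,
                            double bx, double by, double cx, double cy) {
  double d1 = (px - bx) * (ay - by) - (ax - bx) * (py - by);
  double d2 = (px - cx) * (by - cy) - (bx - cx) * (py - cy);
  double d3 = (px - ax) * (cy - ay) - (cx - ax) * (py - ay);
  bool neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
  bool pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
  return !(neg && pos);
}

// Does segment p-q intersect triangle a-b-c (inclusive of boundary)?
static bool seg_tri_intersect(const double *p, const double *q,
                              const double *a, const double *b,
                              const double *c) {
  double ab[3], ac[3], n[3];
  vsub(b, a, ab);
  vsub(c, a, ac);
  vcross(ab, ac, n);
  double nn = std::sqrt(vdot(n, n));
  if (nn < 1e-12) return false;  // degenerate triangle: no area to pierce
  double pa[3], qa[3];
  vsub(p, a, pa);
  vsub(q, a, qa);
  double d1 = vdot(n, pa), d2 = vdot(n, qa);
  double tol = 1e-9 * nn;
  if (std::fabs(d1) < tol && std::fabs(d2) < tol) {
    // coplanar: 2D overlap test on the dominant plane of n
    int ax0 = 0, ax1 = 1;
    double anx = std::fabs(n[0]), any = std::fabs(n[1]), anz = std::fabs(n[2]);
    if (anx >= any && anx >= anz) { ax0 = 1; ax1 = 2; }
    else if (any >= anz) { ax0 = 0; ax1 = 2; }
    double A0 = a[ax0], A1 = a[ax1], B0 = b[ax0], B1 = b[ax1],
           C0 = c[ax0], C1 = c[ax1], P0 = p[ax0], P1 = p[ax1],
           Q0 = q[ax0], Q1 = q[ax1];
    if (point_in_tri_2d(P0, P1, A0, A1, B0, B1, C0, C1)) return true;
    if (point_in_tri_2d(Q0, Q1, A0, A1, B0, B1, C0, C1)) return true;
    if (seg_seg_2d(P0, P1, Q0, Q1, A0, A1, B0, B1)) return true;
    if (seg_seg_2d(P0, P1, Q0, Q1, B0, B1, C0, C1)) return true;
    if (seg_seg_2d(P0, P1, Q0, Q1, C0, C1, A0, A1)) return true;
    return false;
  }
  if (d1 * d2 > tol * tol) return false;  // strictly same side
  double den = d1 - d2;
  if (std::fabs(den) < 1e-15) return false;
  double t = d1 / den;
  if (t < -1e-9 || t > 1 + 1e-9) return false;
  double w[3];
  for (int d = 0; d < 3; ++d) w[d] = pa[d] + t * (qa[d] - pa[d]);
  // barycentric inside test
  double uu = vdot(ab, ab), uv = vdot(ab, ac), vv = vdot(ac, ac);
  double wu = vdot(w, ab), wv = vdot(w, ac);
  double D = uv * uv - uu * vv;
  if (std::fabs(D) < 1e-18) return false;
  double s = (uv * wv - vv * wu) / D;
  double tt = (uv * wu - uu * wv) / D;
  return s >= -1e-7 && tt >= -1e-7 && (s + tt) <= 1 + 1e-7;
}

// KMT reduction: iteratively delete vertex i when triangle (i-1, i, i+1)
// is pierced by no other chain segment. Endpoints of an open chain are
// never removed; a closed chain wraps around.
// [[Rcpp::export]]
NumericMatrix cpp_kmt(NumericMatrix pts, bool closed) {
  int n = pts.nrow();
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) P[3 * i + d] = pts(i, d);
  std::vector<int> act(n);
  for (int i = 0; i < n; ++i) act[i] = i;

  bool removed = true;
  while (removed && (int)act.size() > (closed ? 3 : 2)) {
    removed = false;
    int m = act.size();
    int lo = closed ? 0 : 1;
    int hi = closed ? m : m - 1;
    for (int k = lo; k < hi && (int)act.size() > (closed ? 3 : 2); ++k) {
      m = act.size();
      if (k >= (closed ? m : m - 1)) break;
      int kp = (k - 1 + m) % m, kn = (k + 1) % m;
      if (!closed && (k == 0 || k == m - 1)) continue;
      const double *a = &P[3 * act[kp]];
      const double *v = &P[3 * act[k]];
      const double *b = &P[3 * act[kn]];
      // degenerate (collinear) triangles are always removable
      double e1[3], e2[3], cr[3];
      vsub(v, a, e1);
      vsub(b, a, e2);
      vcross(e1, e2, cr);
      bool blocked = false;
      if (std::sqrt(vdot(cr, cr)) > 1e-10) {
        int nseg = closed ? m : m - 1;
        for (int s = 0; s < nseg; ++s) {
          int s2 = (s + 1) % m;
          // skip segments sharing a vertex with the triangle
          if (s == kp || s == k || s2 == kp || s2 == k || s2 == kn || s == kn)
            continue;
          if (seg_tri_intersect(&P[3 * act[s]], &P[3 * act[s2]], a, v, b)) {
            blocked = true;
            break;
          }
        }
      }
      if (!blocked) {
        act.erase(act.begin() + k);
        --k;
        removed = true;
      }
    }
  }
  NumericMatrix out(act.size(), 3);
  for (size_t i = 0; i < act.size(); ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = P[3 * act[i] + d];
  return out;
}

// Crossings of the xy-projection of a closed polygon. Returns per crossing
// the two segments, curve parameters, and which strand passes over, plus a
// degeneracy flag (vertex-grazing, parallel overlap, or z-ties) telling the
// caller to retry under a different rotation.
// [[Rcpp::export]]
List cpp_crossings(NumericMatrix pts) {
  const int n = pts.nrow();
  std::vector<int> si, sj;
  std::vector<double> ti, tj;
  std::vector<int> over_first;
  bool degenerate = false;
  const double tol = 1e-7;
  for (int i = 0; i < n && !degenerate; ++i) {
    int i2 = (i + 1) % n;
    double ax = pts(i, 0), ay = pts(i, 1);
    double rx = pts(i2, 0) - ax, ry = pts(i2, 1) - ay;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (j == i || j2 == i || j == i2 || (i == 0 && j2 == 0)) continue;
      if (j == i + 1 || (i == 0 && j == n - 1)) continue;
      double cx = pts(j, 0), cy = pts(j, 1);
      double sx = pts(j2, 0) - cx, sy = pts(j2, 1) - cy;
      double den = rx * sy - ry * sx;
      double qpx = cx - ax, qpy = cy - ay;
      if (std::fabs(den) < 1e-13) {
        // parallel projections: degenerate only if collinear and overlapping
        if (std::fabs(qpx * ry - qpy * rx) < 1e-9) {
          double rr = rx * rx + ry * ry;
          if (rr > 1e-18) {
            double t0 = (qpx * rx + qpy * ry) / rr;
            double t1 = t0 + (sx * rx + sy * ry) / rr;
            if (t0 > t1) std::swap(t0, t1);
            if (t1 >= -tol && t0 <= 1 + tol) { degenerate = true; break; }
          }
        }
        continue;
      }
      double t = (qpx * sy - qpy * sx) / den;
      double u = (qpx * ry - qpy * rx) / den;
      if (t <= -tol || t >= 1 + tol || u <= -tol || u >= 1 + tol) continue;
      if (t < tol || t > 1 - tol || u < tol || u > 1 - tol) {
        degenerate = true;
        break;
      }
      double zi = pts(i, 2) + t * (pts(i2, 2) - pts(i, 2));
      double zj = pts(j, 2) + u * (pts(j2, 2) - pts(j, 2));
      if (std::fabs(zi - zj) < 1e-7) { degenerate = true; break; }
      si.push_back(i);
      ti.push_back(t);
      sj.push_back(j);
      tj.push_back(u);
      over_first.push_back(zi > zj ? 1 : 0);
    }
  }
  return List::create(_["degenerate"] = degenerate, _["si"] = wrap(si),
                      _["ti"] = wrap(ti), _["sj"] = wrap(sj),
                      _["tj"] = wrap(tj), _["over_first"] = wrap(over_first));
}
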