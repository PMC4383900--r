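// Core geometry and invariant kernels.
//
// Everything here operates on closed polygonal curves in R^3 given as
// n x 3 coordinate matrices (vertex i is joined to i+1, last to first).
// The hot path (random-closure sampling over all subchains) lives in
// closure_signatures_cpp; the R level only orchestrates.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

typedef __int128 int128;

// ---------------------------------------------------------------- vectors

struct V3 { double x, y, z; };

static inline V3 v3(double x, double y, double z) { V3 v; v.x = x; v.y = y; v.z = z; return v; }
static inline V3 sub(const V3 &a, const V3 &b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 add(const V3 &a, const V3 &b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 scl(const V3 &a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
static inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm3(const V3 &a) { return std::sqrt(dot(a, a)); }

// signed volume of tetrahedron (a,b,c,d) * 6
static inline double orient3d(const V3 &a, const V3 &b, const V3 &c, const V3 &d) {
  return dot(cross(sub(b, a), sub(c, a)), sub(d, a));
}

static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

// ------------------------------------------- segment-triangle intersection

// 2D conservative segment-segment test (closed segments, tolerance tol).
static bool seg_seg_2d(double p1x, double p1y, double p2x, double p2y,
                       double q1x, double q1y, double q2x, double q2y,
                       double tol) {
  double rx = p2x - p1x, ry = p2y - p1y;
  double sx = q2x - q1x, sy = q2y - q1y;
  double denom = cross2(rx, ry, sx, sy);
  double qpx = q1x - p1x, qpy = q1y - p1y;
  double lr = std::sqrt(rx * rx + ry * ry), ls = std::sqrt(sx * sx + sy * sy);
  double scale = std::max(lr * ls, 1e-300);
  if (std::fabs(denom) <= tol * scale) {
    // parallel: intersect only if collinear and overlapping
    if (std::fabs(cross2(qpx, qpy, rx, ry)) > tol * std::max(lr * lr, ls * ls))
      return false;
    // collinear: check 1D overlap along r
    double t0 = (qpx * rx + qpy * ry);
    double t1 = t0 + (sx * rx + sy * ry);
    double lo = std::min(t0, t1), hi = std::max(t0, t1);
    return hi >= -tol * scale && lo <= lr * lr + tol * scale;
  }
  double t = cross2(qpx, qpy, sx, sy) / denom;
  double u = cross2(qpx, qpy, rx, ry) / denom;
  double m = tol;
  return t >= -m && t <= 1 + m && u >= -m && u <= 1 + m;
}

// conservative 2D point-in-triangle
static bool pt_in_tri_2d(double px, double py, double ax, double ay,
                         double bx, double by, double cx, double cy, double tol) {
  double d1 = cross2(bx - ax, by - ay, px - ax, py - ay);
  double d2 = cross2(cx - bx, cy - by, px - bx, py - by);
  double d3 = cross2(ax - cx, ay - cy, px - cx, py - cy);
  double area = std::fabs(cross2(bx - ax, by - ay, cx - ax, cy - ay));
  double m = tol * std::max(area, 1e-300);
  bool has_neg = (d1 < -m) || (d2 < -m) || (d3 < -m);
  bool has_pos = (d1 > m) || (d2 > m) || (d3 > m);
  return !(has_neg && has_pos);
}

// Project points to the coordinate plane most orthogonal to n.
static void plane_axes(const V3 &n, int &ax1, int &ax2) {
  double nx = std::fabs(n.x), ny = std::fabs(n.y), nz = std::fabs(n.z);
  if (nz >= nx && nz >= ny) { ax1 = 0; ax2 = 1; }
  else if (ny >= nx)        { ax1 = 0; ax2 = 2; }
  else                      { ax1 = 1; ax2 = 2; }
}

static inline double coord(const V3 &v, int ax) {
  return ax == 0 ? v.x : (ax == 1 ? v.y : v.z);
}

// Does segment p-q meet the closed triangle (a,b,c)?  Conservative: any
// contact within tolerance counts as an intersection.
static bool seg_tri_intersect(const V3 &p, const V3 &q,
                              const V3 &a, const V3 &b, const V3 &c,
                              double tol) {
  // characteristic scale for the volume tolerances
  double L = 0.0;
  const V3 *pts[5] = { &p, &q, &a, &b, &c };
  for (int i = 0; i < 5; i++)
    for (int j = i + 1; j < 5; j++)
      L = std::max(L, norm3(sub(*pts[i], *pts[j])));
  double tolV = tol * L * L * L;

  double o1 = orient3d(a, b, c, p);
  double o2 = orient3d(a, b, c, q);
  if (o1 > tolV && o2 > tolV) return false;
  if (o1 < -tolV && o2 < -tolV) return false;

  bool cop1 = std::fabs(o1) <= tolV, cop2 = std::fabs(o2) <= tolV;
  if (cop1 && cop2) {
    // coplanar: 2D overlap test in the triangle's plane
    V3 n = cross(sub(b, a), sub(c, a));
    if (norm3(n) <= tol * L * L) return true; // degenerate triangle: be safe
    int ax1, ax2;
    plane_axes(n, ax1, ax2);
    double px = coord(p, ax1), py = coord(p, ax2);
    double qx = coord(q, ax1), qy = coord(q, ax2);
    double axx = coord(a, ax1), axy = coord(a, ax2);
    double bxx = coord(b, ax1), bxy = coord(b, ax2);
    double cxx = coord(c, ax1), cxy = coord(c, ax2);
    if (pt_in_tri_2d(px, py, axx, axy, bxx, bxy, cxx, cxy, tol)) return true;
    if (pt_in_tri_2d(qx, qy, axx, axy, bxx, bxy, cxx, cxy, tol)) return true;
    if (seg_seg_2d(px, py, qx, qy, axx, axy, bxx, bxy, tol)) return true;
    if (seg_seg_2d(px, py, qx, qy, bxx, bxy, cxx, cxy, tol)) return true;
    if (seg_seg_2d(px, py, qx, qy, cxx, cxy, axx, axy, tol)) return true;
    return false;
  }

  // the segment crosses (or touches) the supporting plane: side test
  double s1 = orient3d(p, q, a, b);
  double s2 = orient3d(p, q, b, c);
  double s3 = orient3d(p, q, c, a);
  bool pos = (s1 > tolV) || (s2 > tolV) || (s3 > tolV);
  bool neg = (s1 < -tolV) || (s2 < -tolV) || (s3 < -tolV);
  if (pos && neg) return false;
  return true;
}

// Segment with one endpoint equal to a triangle corner: does it touch the
// triangle anywhere besides that corner?  Used for the two chain segments
// adjacent to a KMT triangle.
static bool seg_tri_from_corner(const V3 &corner, const V3 &other,
                                const V3 &b, const V3 &c, double tol) {
  V3 e1 = sub(b, corner), e2 = sub(c, corner);
  V3 n = cross(e1, e2);
  double L = std::max(norm3(e1), std::max(norm3(e2), norm3(sub(other, corner))));
  double nn = norm3(n);
  if (nn <= tol * L * L) return true; // degenerate triangle: be safe
  double d = dot(n, sub(other, corner)) / nn;
  if (std::fabs(d) > tol * L) return false; // leaves the plane immediately
  // in-plane: is the direction inside the wedge spanned by e1, e2?
  V3 w = sub(other, corner);
  if (norm3(w) <= tol * L) return false; // zero-length
  // solve w = alpha e1 + beta e2 (least squares in-plane)
  double a11 = dot(e1, e1), a12 = dot(e1, e2), a22 = dot(e2, e2);
  double r1 = dot(w, e1), r2 = dot(w, e2);
  double det = a11 * a22 - a12 * a12;
  if (std::fabs(det) <= tol * a11 * a22) return true; // ill-conditioned: be safe
  double alpha = (a22 * r1 - a12 * r2) / det;
  double beta = (a11 * r2 - a12 * r1) / det;
  return alpha >= -tol && beta >= -tol;
}

// [[Rcpp::export]]
bool seg_tri_intersect_cpp(NumericVector p, NumericVector q,
                           NumericVector a, NumericVector b, NumericVector c,
                           double tol) {
  return seg_tri_intersect(v3(p[0], p[1], p[2]), v3(q[0], q[1], q[2]),
                           v3(a[0], a[1], a[2]), v3(b[0], b[1], b[2]),
                           v3(c[0], c[1], c[2]), tol);
}

// ---------------------------------------------------------- KMT reduction

static std::vector<V3> mat_to_pts(const NumericMatrix &m) {
  std::vector<V3> pts(m.nrow());
  for (int i = 0; i < m.nrow(); i++) pts[i] = v3(m(i, 0), m(i, 1), m(i, 2));
  return pts;
}

// Reduce a closed polygon by iterated triangle elimination; returns the
// indices (into pts) of the surviving vertices, in order.
// Drop vertices lying exactly on the segment joining their neighbours
// (the cleaned curve is pointwise identical, so this is always safe).
// Straight runs would otherwise make every projection degenerate.
static void collinear_clean(const std::vector<V3> &pts, std::vector<int> &alive) {
  bool cchanged = true;
  while (cchanged && (int)alive.size() > 3) {
    cchanged = false;
    int m = (int)alive.size();
    for (int i = 0; i < m && m > 3; i++) {
      int ip = (i - 1 + m) % m, in = (i + 1) % m;
      const V3 &A = pts[alive[ip]], &B = pts[alive[i]], &C = pts[alive[in]];
      double ab = norm3(sub(B, A)), bc = norm3(sub(C, B)), ac = norm3(sub(C, A));
      if (ac > 1e-300 && ab + bc - ac <= 1e-9 * ac) {
        alive.erase(alive.begin() + i);
        m--; i--;
        cchanged = true;
      }
    }
  }
}

static std::vector<int> kmt_alive(const std::vector<V3> &pts, double tol,
                                  int *passes_out = 0) {
  int n = (int)pts.size();
  std::vector<int> alive(n);
  for (int i = 0; i < n; i++) alive[i] = i;
  collinear_clean(pts, alive);
  bool changed = true;
  int passes = 0;
  while (changed && (int)alive.size() > 3) {
    changed = false;
    passes++;
    int m = (int)alive.size();
    for (int i = 0; i < m && m > 3; i++) {
      int ip = (i - 1 + m) % m, in = (i + 1) % m;
      const V3 &A = pts[alive[ip]], &B = pts[alive[i]], &C = pts[alive[in]];
      // degenerate triangle: skip (conservative; costs only speed)
      V3 nrm = cross(sub(B, A), sub(C, A));
      double L = std::max(norm3(sub(B, A)), std::max(norm3(sub(C, B)), norm3(sub(C, A))));
      if (norm3(nrm) <= tol * std::max(L * L, 1e-30)) continue;
      bool blocked = false;
      for (int s = 0; s < m && !blocked; s++) {
        int sn = (s + 1) % m;
        if (s == ip || s == i) continue; // triangle's own edges
        bool s_shares = (s == in) || (sn == ip);
        if (s_shares) {
          // segment sharing exactly one corner with the triangle
          if (sn == ip && s == in) continue; // quadrilateral: opposite side
          if (s == in) {
            // segment C -> next
            if (seg_tri_from_corner(C, pts[alive[sn]], A, B, tol)) blocked = true;
          } else {
            // segment prev-1 -> A
            if (seg_tri_from_corner(A, pts[alive[s]], B, C, tol)) blocked = true;
          }
        } else {
          if (seg_tri_intersect(pts[alive[s]], pts[alive[sn]], A, B, C, tol))
            blocked = true;
        }
      }
      if (!blocked) {
        alive.erase(alive.begin() + i);
        m--;
        i--; // re-examine the triangle now ending here
        changed = true;
      }
    }
  }
  if (passes_out) *passes_out = passes;
  return alive;
}

// [[Rcpp::export]]
List kmt_reduce_cpp(NumericMatrix polygon, double tol) {
  std::vector<V3> pts = mat_to_pts(polygon);
  int passes = 0;
  std::vector<int> alive = kmt_alive(pts, tol, &passes);
  NumericMatrix out((int)alive.size(), 3);
  for (int i = 0; i < (int)alive.size(); i++) {
    out(i, 0) = pts[alive[i]].x;
    out(i, 1) = pts[alive[i]].y;
    out(i, 2) = pts[alive[i]].z;
  }
  return List::create(_["polygon"] = out, _["passes"] = passes);
}

// -------------------------------------------------- projection to diagram

struct GaussEntry { int crossing; int over; int sign; };

// Project the closed polygon along unit direction dir and extract the
// signed Gauss code (passages in curve order).  Returns false on any
// near-degenerate configuration (caller redraws the direction).
static bool project_gauss(const std::vector<V3> &pts, const V3 &dir,
                          double tol, std::vector<GaussEntry> &gauss) {
  int n = (int)pts.size();
  // orthonormal frame (e1, e2, dir)
  V3 up = std::fabs(dir.x) < 0.9 ? v3(1, 0, 0) : v3(0, 1, 0);
  V3 e1 = cross(up, dir);
  double l1 = norm3(e1);
  if (l1 < 1e-12) return false;
  e1 = scl(e1, 1.0 / l1);
  V3 e2 = cross(dir, e1);

  std::vector<double> X(n), Y(n), D(n);
  double scale = 0.0;
  for (int i = 0; i < n; i++) {
    X[i] = dot(pts[i], e1);
    Y[i] = dot(pts[i], e2);
    D[i] = dot(pts[i], dir);
    scale = std::max(scale, std::fabs(X[i]) + std::fabs(Y[i]));
  }
  scale = std::max(scale, 1e-12);

  // reject directions nearly parallel to an edge
  for (int i = 0; i < n; i++) {
    int j = (i + 1) % n;
    double dx = X[j] - X[i], dy = Y[j] - Y[i];
    double l2d = std::sqrt(dx * dx + dy * dy);
    double l3d = norm3(sub(pts[j], pts[i]));
    if (l2d < 1e-7 * std::max(l3d, 1e-300)) return false;
  }

  struct Hit { int seg_a, seg_b; double ta, tb; int a_over; int sign; };
  std::vector<Hit> hits;
  double m = 1e-9; // parameter margin for degeneracy calls

  for (int i = 0; i < n; i++) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; j++) {
      int j2 = (j + 1) % n;
      if (j == i2 || j2 == i) continue; // adjacent segments
      double rx = X[i2] - X[i], ry = Y[i2] - Y[i];
      double sx = X[j2] - X[j], sy = Y[j2] - Y[j];
      double denom = cross2(rx, ry, sx, sy);
      double qpx = X[j] - X[i], qpy = Y[j] - Y[i];
      double lr = std::sqrt(rx * rx + ry * ry), ls = std::sqrt(sx * sx + sy * sy);
      if (std::fabs(denom) <= 1e-12 * lr * ls) {
        // parallel in projection: degenerate only if collinear AND the
        // 1D ranges overlap (disjoint pieces of one straight line are
        // harmless and common after interrupted straight runs)
        if (std::fabs(cross2(qpx, qpy, rx, ry)) <= 1e-9 * lr * scale) {
          double t0 = (qpx * rx + qpy * ry) / (lr * lr);
          double t1 = t0 + (sx * rx + sy * ry) / (lr * lr);
          double lo = std::min(t0, t1), hi = std::max(t0, t1);
          if (hi >= -1e-9 && lo <= 1 + 1e-9) return false;
        }
        continue;
      }
      double t = cross2(qpx, qpy, sx, sy) / denom;
      double u = cross2(qpx, qpy, rx, ry) / denom;
      if (t < -m || t > 1 + m || u < -m || u > 1 + m) continue;
      if (t < m || t > 1 - m || u < m || u > 1 - m) return false; // endpoint hit
      double d1 = D[i] + t * (D[i2] - D[i]);
      double d2 = D[j] + u * (D[j2] - D[j]);
      if (std::fabs(d1 - d2) <= 1e-9 * scale) return false; // depth tie
      Hit h;
      h.seg_a = i; h.seg_b = j; h.ta = t; h.tb = u;
      h.a_over = d1 > d2 ? 1 : 0;
      // sign by right-hand rule: positive when (over dir, under dir) is
      // a positively oriented 2D frame
      double s2d;
      if (h.a_over) s2d = cross2(rx, ry, sx, sy);
      else          s2d = cross2(sx, sy, rx, ry);
      h.sign = s2d > 0 ? 1 : -1;
      hits.push_back(h);
    }
  }

  // triple-point guard: two hits on one segment at nearly equal parameter
  int nc = (int)hits.size();
  std::vector<std::vector<std::pair<double, int> > > per_seg(n); // (param, hit*2+side)
  for (int k = 0; k < nc; k++) {
    per_seg[hits[k].seg_a].push_back(std::make_pair(hits[k].ta, 2 * k));
    per_seg[hits[k].seg_b].push_back(std::make_pair(hits[k].tb, 2 * k + 1));
  }
  for (int s = 0; s < n; s++) {
    std::sort(per_seg[s].begin(), per_seg[s].end());
    for (size_t q = 1; q < per_seg[s].size(); q++)
      if (per_seg[s][q].first - per_seg[s][q - 1].first < m) return false;
  }

  gauss.clear();
  for (int s = 0; s < n; s++) {
    for (size_t q = 0; q < per_seg[s].size(); q++) {
      int code = per_seg[s][q].second;
      int k = code / 2;
      bool side_a = (code % 2) == 0;
      GaussEntry e;
      e.crossing = k + 1;
      e.over = side_a ? hits[k].a_over : 1 - hits[k].a_over;
      e.sign = hits[k].sign;
      gauss.push_back(e);
    }
  }
  return true;
}

// [[Rcpp::export]]
List project_gauss_cpp(NumericMatrix polygon, NumericVector dir, double tol) {
  std::vector<V3> raw = mat_to_pts(polygon);
  std::vector<int> alive(raw.size());
  for (size_t i = 0; i < raw.size(); i++) alive[i] = (int)i;
  collinear_clean(raw, alive);
  std::vector<V3> pts(alive.size());
  for (size_t i = 0; i < alive.size(); i++) pts[i] = raw[alive[i]];
  double l = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
  std::vector<GaussEntry> gauss;
  bool ok = project_gauss(pts, v3(dir[0] / l, dir[1] / l, dir[2] / l), tol, gauss);
  if (!ok) return List::create(_["ok"] = false);
  IntegerMatrix g((int)gauss.size(), 3);
  for (int i = 0; i < (int)gauss.size(); i++) {
    g(i, 0) = gauss[i].crossing;
    g(i, 1) = gauss[i].over;
    g(i, 2) = gauss[i].sign;
  }
  colnames(g) = CharacterVector::create("crossing", "over", "sign");
  return List::create(_["ok"] = true, _["gauss"] = g);
}

// ------------------------------------------------- Alexander polynomial

// polynomials over Z as coefficient vectors (degree 0 first), int128
typedef std::vector<int128> Poly;

static void ptrim(Poly &p) {
  while (!p.empty() && p.back() == 0) p.pop_back();
}

static Poly pmul(const Poly &a, const Poly &b) {
  if (a.empty() || b.empty()) return Poly();
  Poly r(a.size() + b.size() - 1, 0);
  for (size_t i = 0; i < a.size(); i++)
    if (a[i] != 0)
      for (size_t j = 0; j < b.size(); j++) r[i + j] += a[i] * b[j];
  ptrim(r);
  return r;
}

static Poly psub(const Poly &a, const Poly &b) {
  Poly r(std::max(a.size(), b.size()), 0);
  for (size_t i = 0; i < a.size(); i++) r[i] += a[i];
  for (size_t i = 0; i < b.size(); i++) r[i] -= b[i];
  ptrim(r);
  return r;
}

// exact division (throws if not exact)
static Poly pdivexact(const Poly &a, const Poly &b) {
  if (a.empty()) return Poly();
  if (b.empty()) stop("polynomial division by zero");
  Poly r = a, q(a.size() - b.size() + 1, 0);
  int db = (int)b.size() - 1;
  for (int i = (int)r.size() - 1; i >= db; i--) {
    if (r[i] == 0) continue;
    if (r[i] % b[db] != 0) stop("inexact polynomial division");
    int128 c = r[i] / b[db];
    q[i - db] = c;
    for (int j = 0; j <= db; j++) r[i - db + j] -= c * b[j];
  }
  for (size_t i = 0; i < r.size(); i++)
    if (r[i] != 0) stop("inexact polynomial division (remainder)");
  ptrim(q);
  return q;
}

// Alexander polynomial (normalized: lowest coefficient nonzero, value +1
// at t = 1) from a signed Gauss code.  gauss rows: (crossing, over, sign)
// in curve order; crossing ids 1..n each appearing once over, once under.
static std::vector<double> alexander_from_gauss(const IntegerMatrix &gauss) {
  int rows = gauss.nrow();
  if (rows == 0) return std::vector<double>(1, 1.0);
  if (rows % 2 != 0) stop("malformed Gauss code: odd number of passages");
  int n = rows / 2;

  // arc assignment: under-passages delimit arcs
  std::vector<int> upos;
  for (int p = 0; p < rows; p++)
    if (gauss(p, 1) == 0) upos.push_back(p);
  if ((int)upos.size() != n) stop("malformed Gauss code: over/under imbalance");

  // arc index for a position: arc k covers (upos[k-1], upos[k]] cyclically
  std::vector<int> arc_of(rows);
  for (int p = 0; p < rows; p++) {
    int k = (int)(std::lower_bound(upos.begin(), upos.end(), p) - upos.begin());
    arc_of[p] = k % n;
  }

  // rows of the Alexander matrix, one per crossing
  std::vector<int> over_arc(n + 1, -1), in_arc(n + 1, -1), out_arc(n + 1, -1), sgn(n + 1, 0);
  for (int p = 0; p < rows; p++) {
    int c = gauss(p, 0);
    if (c < 1 || c > n) stop("malformed Gauss code: bad crossing id");
    if (gauss(p, 1) == 1) {
      if (over_arc[c] != -1) stop("malformed Gauss code: duplicate over-passage");
      over_arc[c] = arc_of[p];
    } else {
      if (in_arc[c] != -1) stop("malformed Gauss code: duplicate under-passage");
      in_arc[c] = arc_of[p];
      out_arc[c] = (arc_of[p] + 1) % n;
    }
    sgn[c] = gauss(p, 2);
  }
  for (int c = 1; c <= n; c++)
    if (over_arc[c] < 0 || in_arc[c] < 0)
      stop("malformed Gauss code: crossing lacks over or under passage");

  if (n == 1) return std::vector<double>(1, 1.0);

  // matrix entries: degree <= 1 polynomials; drop last row, first column
  int msize = n - 1;
  std::vector<std::vector<Poly> > M(msize, std::vector<Poly>(msize));
  Poly one(1, 1), minus_one(1, -1), t_poly(2, 0), one_minus_t(2, 0), t_minus_one(2, 0), minus_t(2, 0);
  t_poly[1] = 1;
  one_minus_t[0] = 1; one_minus_t[1] = -1;
  t_minus_one[0] = -1; t_minus_one[1] = 1;
  minus_t[1] = -1;
  for (int c = 1; c <= msize; c++) { // rows 0..n-2 (crossing c-? use crossings 1..n-1)
    std::vector<Poly> full(n);
    Poly *po, *pi, *pk;
    if (sgn[c] > 0) { po = &one_minus_t; pi = &t_poly; pk = &minus_one; }
    else            { po = &t_minus_one; pi = &one; pk = &minus_t; }
    // accumulate (kinks can put two contributions on one arc)
    std::vector<Poly> acc(n);
    const int arcs[3] = { over_arc[c], in_arc[c], out_arc[c] };
    Poly *vals[3] = { po, pi, pk };
    for (int q = 0; q < 3; q++) {
      Poly &dst = acc[arcs[q]];
      Poly tmp(std::max(dst.size(), vals[q]->size()), 0);
      for (size_t i = 0; i < dst.size(); i++) tmp[i] += dst[i];
      for (size_t i = 0; i < vals[q]->size(); i++) tmp[i] += (*vals[q])[i];
      ptrim(tmp);
      dst = tmp;
    }
    for (int j = 1; j < n; j++) M[c - 1][j - 1] = acc[j];
  }

  // fraction-free (Bareiss) elimination over Z[t]
  int sign_det = 1;
  Poly prev = one;
  for (int k = 0; k < msize; k++) {
    if (M[k][k].empty()) {
      int r = -1;
      for (int i = k + 1; i < msize; i++)
        if (!M[i][k].empty()) { r = i; break; }
      if (r < 0) return std::vector<double>(1, 0.0); // zero determinant
      std::swap(M[k], M[r]);
      sign_det = -sign_det;
    }
    for (int i = k + 1; i < msize; i++) {
      for (int j = k + 1; j < msize; j++) {
        Poly num = psub(pmul(M[k][k], M[i][j]), pmul(M[i][k], M[k][j]));
        M[i][j] = num.empty() ? num : pdivexact(num, prev);
      }
      M[i][k].clear();
    }
    prev = M[k][k];
  }
  Poly det = M[msize - 1][msize - 1];
  if (sign_det < 0) for (size_t i = 0; i < det.size(); i++) det[i] = -det[i];
  if (det.empty()) return std::vector<double>(1, 0.0);

  // normalize: strip t^v, then fix the sign so that P(1) = +1
  size_t v = 0;
  while (v < det.size() && det[v] == 0) v++;
  Poly norm(det.begin() + v, det.end());
  int128 at1 = 0;
  for (size_t i = 0; i < norm.size(); i++) at1 += norm[i];
  if (at1 < 0) for (size_t i = 0; i < norm.size(); i++) norm[i] = -norm[i];
  std::vector<double> out(norm.size());
  for (size_t i = 0; i < norm.size(); i++) {
    double x = (double)norm[i];
    if (std::fabs(x) > 9.0e15) stop("Alexander coefficient overflow");
    out[i] = x;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector alexander_coeffs_cpp(IntegerMatrix gauss) {
  std::vector<double> c = alexander_from_gauss(gauss);
  return NumericVector(c.begin(), c.end());
}

// ------------------------------------------------------ closure building

static std::vector<V3> build_closure(const std::vector<V3> &chain,
                                     const V3 &A, const V3 &B,
                                     const V3 &center, double radius,
                                     double arc_step_deg) {
  std::vector<V3> poly = chain;
  poly.push_back(A);
  V3 ua = sub(A, center), ub = sub(B, center);
  double la = norm3(ua), lb = norm3(ub);
  ua = scl(ua, 1.0 / la);
  ub = scl(ub, 1.0 / lb);
  double cosw = std::max(-1.0, std::min(1.0, dot(ua, ub)));
  double theta = std::acos(cosw);
  double step = arc_step_deg * M_PI / 180.0;
  int nsteps = (int)std::ceil(theta / step);
  if (nsteps > 1) {
    double sinw = std::sin(theta);
    for (int i = 1; i < nsteps; i++) {
      double t = (double)i / nsteps;
      double w1 = std::sin((1 - t) * theta) / sinw;
      double w2 = std::sin(t * theta) / sinw;
      V3 u = add(scl(ua, w1), scl(ub, w2));
      double lu = norm3(u);
      poly.push_back(add(center, scl(u, radius / lu)));
    }
  }
  poly.push_back(B);
  return poly;
}

// [[Rcpp::export]]
NumericMatrix build_closure_cpp(NumericMatrix chain, NumericVector A, NumericVector B,
                                NumericVector center, double radius, double arc_step_deg) {
  std::vector<V3> pts = mat_to_pts(chain);
  std::vector<V3> poly = build_closure(pts, v3(A[0], A[1], A[2]), v3(B[0], B[1], B[2]),
                                       v3(center[0], center[1], center[2]), radius,
                                       arc_step_deg);
  NumericMatrix out((int)poly.size(), 3);
  for (int i = 0; i < (int)poly.size(); i++) {
    out(i, 0) = poly[i].x; out(i, 1) = poly[i].y; out(i, 2) = poly[i].z;
  }
  return out;
}

// --------------------------------------------------- batched closures

static bool classify_polygon_sig(const std::vector<V3> &poly, double tol,
                                 int max_tries, double &d1, double &d2) {
  std::vector<int> alive = kmt_alive(poly, tol);
  std::vector<V3> red(alive.size());
  for (size_t i = 0; i < alive.size(); i++) red[i] = poly[alive[i]];
  std::vector<GaussEntry> gauss;
  for (int tries = 0; tries < max_tries; tries++) {
    // random direction on the sphere (uses R RNG)
    double x, y, z, r2;
    do {
      x = norm_rand(); y = norm_rand(); z = norm_rand();
      r2 = x * x + y * y + z * z;
    } while (r2 < 1e-12);
    double l = std::sqrt(r2);
    if (project_gauss(red, v3(x / l, y / l, z / l), tol, gauss)) {
      IntegerMatrix g((int)gauss.size(), 3);
      for (int i = 0; i < (int)gauss.size(); i++) {
        g(i, 0) = gauss[i].crossing; g(i, 1) = gauss[i].over; g(i, 2) = gauss[i].sign;
      }
      std::vector<double> coef = alexander_from_gauss(g);
      double v1 = 0, v2 = 0, p1 = 1, p2 = 1;
      for (size_t i = 0; i < coef.size(); i++) {
        v1 += coef[i] * p1; p1 *= -1.0;
        v2 += coef[i] * p2; p2 *= -2.0;
      }
      d1 = std::fabs(v1);
      d2 = std::fabs(v2);
      return true;
    }
  }
  return false;
}

// Sample random closures of an open subchain through the given closure
// points and return the Alexander signature (|D(-1)|, |D(-2)|) of each.
// Draws (closure pair, projection directions) come from the R RNG so the
// caller's set.seed() governs everything.
// [[Rcpp::export]]
NumericMatrix closure_signatures_cpp(NumericMatrix chain, NumericMatrix closure_pts,
                                     NumericVector center, double radius,
                                     int n_closures, double arc_step_deg,
                                     double tol, int max_proj_tries,
                                     Nullable<IntegerMatrix> pairs = R_NilValue) {
  std::vector<V3> pts = mat_to_pts(chain);
  std::vector<V3> cp = mat_to_pts(closure_pts);
  V3 cen = v3(center[0], center[1], center[2]);
  int np = (int)cp.size();

  IntegerMatrix fixed_pairs;
  bool use_fixed = pairs.isNotNull();
  if (use_fixed) {
    fixed_pairs = IntegerMatrix(pairs);
    n_closures = fixed_pairs.nrow();
  }

  NumericMatrix out(n_closures, 2);
  for (int k = 0; k < n_closures; k++) {
    int a, b;
    if (use_fixed) {
      a = fixed_pairs(k, 0) - 1;
      b = fixed_pairs(k, 1) - 1;
    } else {
      int guard = 0;
      do {
        a = (int)(unif_rand() * np); if (a >= np) a = np - 1;
        b = (int)(unif_rand() * np); if (b >= np) b = np - 1;
        if (++guard > 10000) stop("cannot draw a usable closure pair");
      } while (a == b ||
               dot(scl(sub(cp[a], cen), 1.0 / radius),
                   scl(sub(cp[b], cen), 1.0 / radius)) < -0.995);
    }
    if (a == b) stop("closure pair indices must be distinct");
    std::vector<V3> poly = build_closure(pts, cp[a], cp[b], cen, radius, arc_step_deg);
    double d1, d2;
    if (!classify_polygon_sig(poly, tol, max_proj_tries, d1, d2))
      stop("no generic projection found");
    out(k, 0) = d1;
    out(k, 1) = d2;
  }
  return out;
}
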