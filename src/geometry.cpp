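#include <Rcpp.h>
using namespace Rcpp;

// Planar geometry kernels for polygon rings stored as n x 2 matrices
// (open rings: last vertex != first; closure is implicit).

static inline double sq(double x) { return x * x; }

// squared distance from point p to segment [a, b]
static double pt_seg_d2(double px, double py,
                        double ax, double ay, double bx, double by) {
  double vx = bx - ax, vy = by - ay;
  double wx = px - ax, wy = py - ay;
  double L2 = vx * vx + vy * vy;
  double t = (L2 > 0.0) ? (wx * vx + wy * vy) / L2 : 0.0;
  if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  return sq(px - (ax + t * vx)) + sq(py - (ay + t * vy));
}

static inline double orient(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static bool seg_intersect(double ax, double ay, double bx, double by,
                          double cx, double cy, double dx, double dy) {
  double d1 = orient(cx, cy, dx, dy, ax, ay);
  double d2 = orient(cx, cy, dx, dy, bx, by);
  double d3 = orient(ax, ay, bx, by, cx, cy);
  double d4 = orient(ax, ay, bx, by, dx, dy);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return true;
  return false; // collinear / endpoint contact handled via distance == 0
}

// squared min distance between segments [a,b] and [c,d]; 0 if they cross
static double seg_seg_d2(double ax, double ay, double bx, double by,
                         double cx, double cy, double dx, double dy) {
  if (seg_intersect(ax, ay, bx, by, cx, cy, dx, dy)) return 0.0;
  double m = pt_seg_d2(ax, ay, cx, cy, dx, dy);
  double t = pt_seg_d2(bx, by, cx, cy, dx, dy); if (t < m) m = t;
  t = pt_seg_d2(cx, cy, ax, ay, bx, by); if (t < m) m = t;
  t = pt_seg_d2(dx, dy, ax, ay, bx, by); if (t < m) m = t;
  return m;
}

// even-odd ray casting; returns 1 strictly inside, 0 outside/boundary-ish
static int point_in_ring(double px, double py, const NumericMatrix &P) {
  int n = P.nrow(), inside = 0;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double xi = P(i, 0), yi = P(i, 1), xj = P(j, 0), yj = P(j, 1);
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)) inside = !inside;
  }
  return inside;
}

// [[Rcpp::export]]
int cpp_point_in_poly(double px, double py, NumericMatrix P) {
  return point_in_ring(px, py, P);
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_poly(NumericVector px, NumericVector py,
                                 NumericMatrix P) {
  int n = px.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = point_in_ring(px[i], py[i], P) == 1;
  return out;
}

// minimum distance between the boundaries of rings A and B
static double boundary_dist(const NumericMatrix &A, const NumericMatrix &B) {
  int na = A.nrow(), nb = B.nrow();
  double best = R_PosInf;
  for (int i = 0; i < na; ++i) {
    int i2 = (i + 1) % na;
    double ax = A(i, 0), ay = A(i, 1), bx = A(i2, 0), by = A(i2, 1);
    for (int j = 0; j < nb; ++j) {
      int j2 = (j + 1) % nb;
      double d2 = seg_seg_d2(ax, ay, bx, by,
                             B(j, 0), B(j, 1), B(j2, 0), B(j2, 1));
      if (d2 < best) {
        best = d2;
        if (best == 0.0) return 0.0;
      }
    }
  }
  return std::sqrt(best);
}

// edge-to-edge distance: 0 when boundaries touch/cross or one ring
// contains the other; else the minimum boundary separation
// [[Rcpp::export]]
double cpp_edge_distance(NumericMatrix A, NumericMatrix B) {
  double d = boundary_dist(A, B);
  if (d == 0.0) return 0.0;
  if (point_in_ring(A(0, 0), A(0, 1), B)) return 0.0;
  if (point_in_ring(B(0, 0), B(0, 1), A)) return 0.0;
  return d;
}

// pairwise edge-to-edge distance matrix over a list of rings, with a
// bounding-box gap shortcut skipped: the full value is needed everywhere
// [[Rcpp::export]]
NumericMatrix cpp_dist_matrix(List polys) {
  int n = polys.size();
  NumericMatrix D(n, n);
  std::vector<NumericMatrix> P(n);
  for (int i = 0; i < n; ++i) P[i] = as<NumericMatrix>(polys[i]);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = cpp_edge_distance(P[i], P[j]);
      D(i, j) = d;
      D(j, i) = d;
    }
  return D;
}

// minimum edge-to-edge distance from ring A to any ring in `polys` whose
// bounding box comes within `cutoff` of A's; early exit when < stop_below.
// Returns +Inf when every candidate is prefiltered away.
// [[Rcpp::export]]
double cpp_min_dist_to_set(NumericMatrix A, List polys, double cutoff,
                           double stop_below) {
  int n = polys.size();
  double ax0 = R_PosInf, ax1 = R_NegInf, ay0 = R_PosInf, ay1 = R_NegInf;
  for (int i = 0; i < A.nrow(); ++i) {
    ax0 = std::min(ax0, A(i, 0)); ax1 = std::max(ax1, A(i, 0));
    ay0 = std::min(ay0, A(i, 1)); ay1 = std::max(ay1, A(i, 1));
  }
  double best = R_PosInf;
  for (int k = 0; k < n; ++k) {
    NumericMatrix B = as<NumericMatrix>(polys[k]);
    double bx0 = R_PosInf, bx1 = R_NegInf, by0 = R_PosInf, by1 = R_NegInf;
    for (int i = 0; i < B.nrow(); ++i) {
      bx0 = std::min(bx0, B(i, 0)); bx1 = std::max(bx1, B(i, 0));
      by0 = std::min(by0, B(i, 1)); by1 = std::max(by1, B(i, 1));
    }
    double gx = std::max({0.0, bx0 - ax1, ax0 - bx1});
    double gy = std::max({0.0, by0 - ay1, ay0 - by1});
    if (std::sqrt(gx * gx + gy * gy) > cutoff) continue;
    double d = cpp_edge_distance(A, B);
    if (d < best) best = d;
    if (best < stop_below) return best;
  }
  return best;
}

// do the boundaries of A and B touch or cross (distance 0)?
// [[Rcpp::export]]
bool cpp_boundaries_touch(NumericMatrix A, NumericMatrix B) {
  return boundary_dist(A, B) == 0.0;
}

// overlap classification for simple rings:
//   0 disjoint, 1 proper edge crossing (positive-area overlap),
//   2 containment (positive-area overlap),
//   3 boundary contact without proper crossing (caller must decide)
// [[Rcpp::export]]
int cpp_overlap_state(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  bool touch = false;
  double best = R_PosInf;
  for (int i = 0; i < na; ++i) {
    int i2 = (i + 1) % na;
    double ax = A(i, 0), ay = A(i, 1), bx = A(i2, 0), by = A(i2, 1);
    for (int j = 0; j < nb; ++j) {
      int j2 = (j + 1) % nb;
      double cx = B(j, 0), cy = B(j, 1), dx = B(j2, 0), dy = B(j2, 1);
      if (seg_intersect(ax, ay, bx, by, cx, cy, dx, dy)) return 1;
      double d2 = pt_seg_d2(ax, ay, cx, cy, dx, dy);
      double t = pt_seg_d2(bx, by, cx, cy, dx, dy); if (t < d2) d2 = t;
      t = pt_seg_d2(cx, cy, ax, ay, bx, by); if (t < d2) d2 = t;
      t = pt_seg_d2(dx, dy, ax, ay, bx, by); if (t < d2) d2 = t;
      if (d2 < best) best = d2;
      if (d2 == 0.0) touch = true;
    }
  }
  if (touch) return 3;
  if (point_in_ring(A(0, 0), A(0, 1), B)) return 2;
  if (point_in_ring(B(0, 0), B(0, 1), A)) return 2;
  return 0;
}
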