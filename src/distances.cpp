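#include <Rcpp.h>
using namespace Rcpp;

// Shortest Euclidean distance from each query point to a set of line
// segments. Segment i runs from (ax[i], ay[i]) to (bx[i], by[i]).
// This is the hot loop of boundary-distance metrics: O(n_points * n_segments)
// with exact point-to-segment projection (never point-to-vertex only).
// [[Rcpp::export]]
NumericVector cpp_min_segment_distance(NumericVector px, NumericVector py,
                                       NumericVector ax, NumericVector ay,
                                       NumericVector bx, NumericVector by) {
  const R_xlen_t n = px.size(), m = ax.size();
  if (py.size() != n) stop("point coordinate lengths differ");
  if (ay.size() != m || bx.size() != m || by.size() != m)
    stop("segment coordinate lengths differ");
  if (m == 0) stop("no segments supplied");
  NumericVector out(n);
  std::vector<double> dx(m), dy(m), len2(m);
  for (R_xlen_t j = 0; j < m; ++j) {
    dx[j] = bx[j] - ax[j];
    dy[j] = by[j] - ay[j];
    len2[j] = dx[j] * dx[j] + dy[j] * dy[j];
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    const double x = px[i], y = py[i];
    double best = R_PosInf;
    for (R_xlen_t j = 0; j < m; ++j) {
      double t = 0.0;
      if (len2[j] > 0.0) {
        t = ((x - ax[j]) * dx[j] + (y - ay[j]) * dy[j]) / len2[j];
        if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      }
      const double ex = x - (ax[j] + t * dx[j]);
      const double ey = y - (ay[j] + t * dy[j]);
      const double d2 = ex * ex + ey * ey;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

static inline int orient(double ax, double ay, double bx, double by,
                         double cx, double cy) {
  const double v = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
  if (v > 0) return 1;
  if (v < 0) return -1;
  return 0;
}

static inline bool on_segment(double ax, double ay, double bx, double by,
                              double px, double py) {
  return std::min(ax, bx) <= px && px <= std::max(ax, bx) &&
         std::min(ay, by) <= py && py <= std::max(ay, by);
}

static bool segments_cross(double ax, double ay, double bx, double by,
                           double cx, double cy, double dx, double dy) {
  const int o1 = orient(ax, ay, bx, by, cx, cy);
  const int o2 = orient(ax, ay, bx, by, dx, dy);
  const int o3 = orient(cx, cy, dx, dy, ax, ay);
  const int o4 = orient(cx, cy, dx, dy, bx, by);
  if (o1 != o2 && o3 != o4) return true;
  if (o1 == 0 && on_segment(ax, ay, bx, by, cx, cy)) return true;
  if (o2 == 0 && on_segment(ax, ay, bx, by, dx, dy)) return true;
  if (o3 == 0 && on_segment(cx, cy, dx, dy, ax, ay)) return true;
  if (o4 == 0 && on_segment(cx, cy, dx, dy, bx, by)) return true;
  return false;
}

// TRUE iff the closed ring (x, y) (first vertex NOT repeated at the end)
// has no self-intersection other than shared endpoints of adjacent edges.
// [[Rcpp::export]]
bool cpp_ring_is_simple(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (y.size() != n) stop("coordinate lengths differ");
  if (n < 3) return false;
  for (int i = 0; i < n; ++i) {
    const int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      const int j2 = (j + 1) % n;
      // skip adjacent edges (shared endpoint)
      if (i == j || i2 == j || i == j2) continue;
      if (segments_cross(x[i], y[i], x[i2], y[i2],
                         x[j], y[j], x[j2], y[j2])) return false;
    }
  }
  return true;
}

// Even-odd (ray casting) point-in-polygon for a single ring; boundary
// points may land on either side, callers needing boundary awareness
// must test distance to the boundary separately.
// [[Rcpp::export]]
LogicalVector cpp_points_in_ring(NumericVector px, NumericVector py,
                                 NumericVector rx, NumericVector ry) {
  const R_xlen_t n = px.size(), m = rx.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    bool inside = false;
    for (R_xlen_t j = 0, k = m - 1; j < m; k = j++) {
      if (((ry[j] > py[i]) != (ry[k] > py[i])) &&
          (px[i] < (rx[k] - rx[j]) * (py[i] - ry[j]) / (ry[k] - ry[j]) + rx[j]))
        inside = !inside;
    }
    out[i] = inside;
  }
  return out;
}
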