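#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Pixel grid convention: zero-based continuous coordinates, x = column,
// y = row, pixel centers at integer coordinates. R matrices are indexed
// img(row, col) one-based, so image value at (x, y) is img(y, x) zero-based.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear interpolation with clamping to the image border.
static double bilinear(const NumericMatrix& img, double x, double y) {
  const int h = img.nrow(), w = img.ncol();
  x = clampd(x, 0.0, w - 1.0);
  y = clampd(y, 0.0, h - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 > w - 2) x0 = w - 2;
  if (y0 > h - 2) y0 = h - 2;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  double fx = x - x0, fy = y - y0;
  if (w == 1) { x0 = 0; fx = 0.0; }
  if (h == 1) { y0 = 0; fy = 0.0; }
  const int x1 = (w == 1) ? 0 : x0 + 1, y1 = (h == 1) ? 0 : y0 + 1;
  return img(y0, x0) * (1 - fx) * (1 - fy) + img(y0, x1) * fx * (1 - fy) +
         img(y1, x0) * (1 - fx) * fy + img(y1, x1) * fx * fy;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_sample(const NumericMatrix& img, const NumericVector& x,
                                  const NumericVector& y) {
  const R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = bilinear(img, x[i], y[i]);
  return out;
}

// Node weights of the polar multi-column graph for one seed:
// w[i, j] = I(i, j) + lambda * sum_{i'=1..i} E(i', j), for j = 1..n, plus a
// zero-weight replica column n+1. Rows i = 1..m are radial samples at i*r/m,
// columns j = 1..n are rays at angle 2*pi*j/n. Out-of-image samples clamp to
// the nearest border pixel.
// [[Rcpp::export]]
NumericMatrix cpp_polar_weights(const NumericMatrix& img, const NumericMatrix& edges,
                                double sx, double sy, double r, int n, int m,
                                double lambda) {
  NumericMatrix W(m, n + 1);
  for (int j = 1; j <= n; ++j) {
    const double th = 2.0 * M_PI * j / n;
    const double ct = std::cos(th), st = std::sin(th);
    double esum = 0.0;
    for (int i = 1; i <= m; ++i) {
      const double rad = (double)i * r / m;
      const double x = sx + rad * ct, y = sy + rad * st;
      esum += bilinear(edges, x, y);
      W(i - 1, j - 1) = bilinear(img, x, y) + lambda * esum;
    }
  }
  for (int i = 0; i < m; ++i) W(i, n) = 0.0;
  return W;
}

// Backward DP for a fixed start row s (zero-based) under a row corridor
// [lo[j], hi[j]] per column. g[i][j] = min cost of a path from node (i, j)
// to node (s, n) inclusive of node weights; returns total cost g[s][0] and
// optionally reconstructs the lexicographically smallest optimal row
// sequence (forward greedy over ties).
static double solve_start(const NumericMatrix& W, int s, const int* lo, const int* hi,
                          std::vector<int>* path_out) {
  const int m = W.nrow(), ncol = W.ncol(); // ncol = n + 1
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g((size_t)m * ncol, INF);
  // last column: only the start row may be used (closure)
  if (s >= lo[ncol - 1] && s <= hi[ncol - 1]) g[(size_t)s * ncol + (ncol - 1)] = W(s, ncol - 1);
  for (int j = ncol - 2; j >= 0; --j) {
    const int l = std::max(0, lo[j]), hgh = std::min(m - 1, hi[j]);
    for (int i = l; i <= hgh; ++i) {
      double best = INF;
      for (int d = -1; d <= 1; ++d) {
        const int t = i + d;
        if (t < 0 || t >= m) continue;
        const double v = g[(size_t)t * ncol + (j + 1)];
        if (v < best) best = v;
      }
      if (best < INF) g[(size_t)i * ncol + j] = W(i, j) + best;
    }
  }
  const double cost = (s >= lo[0] && s <= hi[0]) ? g[(size_t)s * ncol] : INF;
  if (path_out != nullptr && std::isfinite(cost)) {
    std::vector<int>& p = *path_out;
    p.assign(ncol, 0);
    p[0] = s;
    int cur = s;
    for (int j = 0; j < ncol - 1; ++j) {
      // re-derive the argmin used by the DP; ties go to the smaller row
      int nxt = -1;
      double best = std::numeric_limits<double>::infinity();
      for (int d = -1; d <= 1; ++d) { // visit rows in increasing order
        const int t = cur + d;
        if (t < 0 || t >= m || t < lo[j + 1] || t > hi[j + 1]) continue;
        const double v = g[(size_t)t * ncol + (j + 1)];
        if (v < best) { best = v; nxt = t; }
      }
      if (nxt < 0) stop("internal error: path reconstruction failed");
      p[j + 1] = nxt;
      cur = nxt;
    }
  }
  return cost;
}

static List path_result(const std::vector<int>& rows, double cost) {
  IntegerVector rv(rows.size());
  for (size_t i = 0; i < rows.size(); ++i) rv[i] = rows[i] + 1; // one-based rows
  return List::create(_["rows"] = rv, _["cost"] = cost);
}

// Naive solver: an O(mn) DP per start row, O(m^2 n) total. Ties among start
// rows broken toward the smaller start row; within a start row the
// lexicographically smallest optimal row sequence is returned.
// [[Rcpp::export]]
List cpp_closed_path_naive(const NumericMatrix& W) {
  const int m = W.nrow(), ncol = W.ncol();
  std::vector<int> lo(ncol, 0), hi(ncol, m - 1);
  double best = std::numeric_limits<double>::infinity();
  int bs = 0;
  for (int s = 0; s < m; ++s) {
    const double c = solve_start(W, s, lo.data(), hi.data(), nullptr);
    if (c < best) { best = c; bs = s; }
  }
  std::vector<int> path;
  solve_start(W, bs, lo.data(), hi.data(), &path);
  return path_result(path, best);
}

struct DCState {
  const NumericMatrix* W;
  std::vector<double> cost;            // per start row
  std::vector<std::vector<int>> path;  // per start row
};

// Recursively solve start rows in [slo, shi] with row corridor given by the
// already-solved enclosing paths (inclusive bounds).
static void dc_solve(DCState& st, int slo, int shi, const std::vector<int>& lo,
                     const std::vector<int>& hi) {
  if (slo > shi) return;
  const int mid = slo + (shi - slo) / 2;
  std::vector<int> path;
  st.cost[mid] = solve_start(*st.W, mid, lo.data(), hi.data(), &path);
  if (!std::isfinite(st.cost[mid])) {
    // corridor excluded this start entirely (cannot happen with inclusive
    // bounds containing row mid at every column, kept for safety)
    path.assign(lo.size(), mid);
  }
  st.path[mid] = path;
  if (slo < mid) dc_solve(st, slo, mid - 1, lo, path);
  if (mid < shi) dc_solve(st, mid + 1, shi, path, hi);
}

// Divide-and-conquer solver, O(mn log m): solve the middle start row, then
// recurse above and below it, constraining each sub-problem to the corridor
// bounded by the enclosing solved paths (non-crossing property of optimal
// paths in the multi-column graph).
// [[Rcpp::export]]
List cpp_closed_path_dc(const NumericMatrix& W) {
  const int m = W.nrow(), ncol = W.ncol();
  DCState st;
  st.W = &W;
  st.cost.assign(m, std::numeric_limits<double>::infinity());
  st.path.assign(m, std::vector<int>());
  std::vector<int> lo(ncol, 0), hi(ncol, m - 1);
  dc_solve(st, 0, m - 1, lo, hi);
  int bs = 0;
  for (int s = 1; s < m; ++s)
    if (st.cost[s] < st.cost[bs]) bs = s;
  return path_result(st.path[bs], st.cost[bs]);
}

// Rasterize a closed polygon given by vertices (vx, vy) in zero-based image
// coordinates. Boundary pixels: 8-connected Bresenham lines between rounded
// consecutive vertices (closed). Region pixels: even-odd scanline fill at
// pixel centers, minus boundary pixels. Pixels outside the image are clamped
// (boundary) or dropped (fill handles bounds directly). Returns one-based
// column-major linear indices into an h x w matrix.
// [[Rcpp::export]]
List cpp_rasterize_polygon(const NumericVector& vx, const NumericVector& vy,
                           int h, int w) {
  const int k = vx.size();
  std::vector<unsigned char> bnd((size_t)h * w, 0), fill((size_t)h * w, 0);
  // boundary
  for (int t = 0; t < k; ++t) {
    const int u = (t + 1) % k;
    long x0 = std::lround(vx[t]), y0 = std::lround(vy[t]);
    long x1 = std::lround(vx[u]), y1 = std::lround(vy[u]);
    long dx = std::labs(x1 - x0), sxs = x0 < x1 ? 1 : -1;
    long dy = -std::labs(y1 - y0), sys = y0 < y1 ? 1 : -1;
    long err = dx + dy;
    while (true) {
      const long cx = std::min<long>(std::max<long>(x0, 0), w - 1);
      const long cy = std::min<long>(std::max<long>(y0, 0), h - 1);
      bnd[(size_t)cx * h + cy] = 1;
      if (x0 == x1 && y0 == y1) break;
      const long e2 = 2 * err;
      if (e2 >= dy) { err += dy; x0 += sxs; }
      if (e2 <= dx) { err += dx; y0 += sys; }
    }
  }
  // even-odd scanline fill at integer pixel centers
  double ymin = vy[0], ymax = vy[0];
  for (int t = 1; t < k; ++t) { ymin = std::min(ymin, vy[t]); ymax = std::max(ymax, vy[t]); }
  const int y0r = std::max(0, (int)std::ceil(ymin));
  const int y1r = std::min(h - 1, (int)std::floor(ymax));
  std::vector<double> xs;
  for (int y = y0r; y <= y1r; ++y) {
    xs.clear();
    for (int t = 0; t < k; ++t) {
      const int u = (t + 1) % k;
      const double ya = vy[t], yb = vy[u];
      if ((ya <= y && yb > y) || (yb <= y && ya > y)) {
        const double x = vx[t] + (y - ya) / (yb - ya) * (vx[u] - vx[t]);
        xs.push_back(x);
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t q = 0; q + 1 < xs.size(); q += 2) {
      int xa = (int)std::ceil(xs[q]);
      int xb = (int)std::ceil(xs[q + 1]) - 1;
      xa = std::max(xa, 0);
      xb = std::min(xb, w - 1);
      for (int x = xa; x <= xb; ++x) fill[(size_t)x * h + y] = 1;
    }
  }
  size_t nb = 0, nr = 0;
  for (size_t i = 0; i < bnd.size(); ++i) {
    if (bnd[i]) ++nb;
    else if (fill[i]) ++nr;
  }
  IntegerVector bi(nb), ri(nr);
  size_t pb = 0, pr = 0;
  for (size_t i = 0; i < bnd.size(); ++i) {
    if (bnd[i]) bi[pb++] = (int)i + 1;
    else if (fill[i]) ri[pr++] = (int)i + 1;
  }
  return List::create(_["boundary_idx"] = bi, _["region_idx"] = ri);
}
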