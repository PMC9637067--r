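// Low-level raster kernels. All coordinates crossing the R boundary are
// 0-based (x = column, y = row); R matrices are indexed [y + 1, x + 1].
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Median filter with edge replication. k odd, >= 3.
// [[Rcpp::export(name = ".median_filter_cpp")]]
IntegerMatrix median_filter_cpp(IntegerMatrix img, int k) {
  int H = img.nrow(), W = img.ncol(), r = k / 2;
  IntegerMatrix out(H, W);
  std::vector<int> buf(k * k);
  int mid = (k * k) / 2;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int n = 0;
      for (int dx = -r; dx <= r; ++dx) {
        int xx = clampi(x + dx, 0, W - 1);
        for (int dy = -r; dy <= r; ++dy) {
          int yy = clampi(y + dy, 0, H - 1);
          buf[n++] = img(yy, xx);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + mid, buf.begin() + n);
      out(y, x) = buf[mid];
    }
  }
  return out;
}

// Separable Gaussian-weighted local mean with edge replication.
// kern is the 1-D normalized kernel of odd length s.
// [[Rcpp::export(name = ".gaussian_local_mean_cpp")]]
NumericMatrix gaussian_local_mean_cpp(NumericMatrix img, NumericVector kern) {
  int H = img.nrow(), W = img.ncol(), s = kern.size(), r = s / 2;
  NumericMatrix tmp(H, W), out(H, W);
  // horizontal pass
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t)
        acc += kern[t + r] * img(y, clampi(x + t, 0, W - 1));
      tmp(y, x) = acc;
    }
  }
  // vertical pass
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t)
        acc += kern[t + r] * tmp(clampi(y + t, 0, H - 1), x);
      out(y, x) = acc;
    }
  }
  return out;
}

// Fixed-range 4-connected flood fill: reachable pixels whose gray differs
// from the seed gray by <= tol, restricted to roi.
// [[Rcpp::export(name = ".flood_fill_cpp")]]
LogicalMatrix flood_fill_cpp(IntegerMatrix gray, LogicalMatrix roi,
                             int sx, int sy, int tol) {
  int H = gray.nrow(), W = gray.ncol();
  LogicalMatrix out(H, W);
  if (sx < 0 || sx >= W || sy < 0 || sy >= H || !roi(sy, sx)) return out;
  int g0 = gray(sy, sx);
  std::queue<std::pair<int, int> > q;
  out(sy, sx) = true;
  q.push(std::make_pair(sx, sy));
  const int dx[4] = {1, -1, 0, 0}, dy[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int d = 0; d < 4; ++d) {
      int x = p.first + dx[d], y = p.second + dy[d];
      if (x < 0 || x >= W || y < 0 || y >= H) continue;
      if (out(y, x) || !roi(y, x)) continue;
      if (std::abs(gray(y, x) - g0) <= tol) {
        out(y, x) = true;
        q.push(std::make_pair(x, y));
      }
    }
  }
  return out;
}

// Connected-component labelling (conn = 4 or 8). Labels 1..n in order of
// first pixel encountered in a row-major scan; 0 = background.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int conn) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  int nd = (conn == 8) ? 8 : 4;
  std::vector<std::pair<int, int> > stack;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      if (!mask(y, x) || lab(y, x)) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(x, y));
      lab(y, x) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back(); stack.pop_back();
        for (int d = 0; d < nd; ++d) {
          int xx = p.first + dx8[d], yy = p.second + dy8[d];
          if (xx < 0 || xx >= W || yy < 0 || yy >= H) continue;
          if (mask(yy, xx) && !lab(yy, xx)) {
            lab(yy, xx) = next;
            stack.push_back(std::make_pair(xx, yy));
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbour boundary trace (clockwise) of one 8-connected component,
// starting at its first row-major pixel (computed, or passed via
// hint_x/hint_y to avoid a full-frame scan). Stops when the initial
// transition start -> second pixel repeats (Jacob's criterion), with a hard
// cap of 4 boundary visits per component pixel (n_pixels) as a safety net.
// Returns an ordered m x 2 matrix of 0-based (x, y) boundary coordinates.
// [[Rcpp::export(name = ".trace_boundary_cpp")]]
IntegerMatrix trace_boundary_cpp(IntegerMatrix lab, int label,
                                 int hint_x = -1, int hint_y = -1,
                                 double n_pixels = -1) {
  int H = lab.nrow(), W = lab.ncol();
  int sx = hint_x, sy = hint_y;
  if (sx < 0 || sy < 0) {
    sx = -1; sy = -1;
    for (int y = 0; y < H && sx < 0; ++y)
      for (int x = 0; x < W; ++x)
        if (lab(y, x) == label) { sx = x; sy = y; break; }
  }
  if (sx < 0) return IntegerMatrix(0, 2);
  // clockwise ring with image y increasing downward:
  // 0=W, 1=NW, 2=N, 3=NE, 4=E, 5=SE, 6=S, 7=SW
  const int dx[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dy[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  auto dir_of = [&](int ox, int oy) {
    for (int d = 0; d < 8; ++d)
      if (dx[d] == ox && dy[d] == oy) return d;
    return 0;
  };
  std::vector<std::pair<int, int> > pts;
  pts.push_back(std::make_pair(sx, sy));
  int px = sx, py = sy;
  int bx = sx - 1, by = sy; // W neighbour of the scan-first pixel is bg
  const int bx0 = bx, by0 = by;
  int p1x = -1, p1y = -1; // second boundary pixel (first move target)
  long guard = (n_pixels > 0) ? (long)(4 * n_pixels) + 16 : 8L * H * W + 64;
  while (guard-- > 0) {
    int ds = dir_of(bx - px, by - py);
    int found = -1, prev = ds;
    for (int i = 1; i <= 8; ++i) {
      int d = (ds + i) % 8;
      int xx = px + dx[d], yy = py + dy[d];
      bool fg = (xx >= 0 && xx < W && yy >= 0 && yy < H &&
                 lab(yy, xx) == label);
      if (fg) { found = d; break; }
      prev = d;
    }
    if (found < 0) break; // isolated single pixel
    bx = px + dx[prev]; by = py + dy[prev];
    int ox = px, oy = py;
    px = px + dx[found]; py = py + dy[found];
    if (px == sx && py == sy && bx == bx0 && by == by0) break; // same backtrack
    if (ox == sx && oy == sy && px == p1x && py == p1y) break; // transition repeat
    if (p1x < 0) { p1x = px; p1y = py; }
    pts.push_back(std::make_pair(px, py));
  }
  IntegerMatrix out(pts.size(), 2);
  for (size_t i = 0; i < pts.size(); ++i) {
    out(i, 0) = pts[i].first;
    out(i, 1) = pts[i].second;
  }
  return out;
}

// ---- Welzl minimum enclosing circle ---------------------------------------

struct Circ { double x, y, r2; };

static inline bool in_circ(const Circ& c, double px, double py) {
  double dx = px - c.x, dy = py - c.y;
  return dx * dx + dy * dy <= c.r2 * (1.0 + 1e-10) + 1e-9;
}

static Circ circ2(double ax, double ay, double bx, double by) {
  Circ c;
  c.x = (ax + bx) / 2.0; c.y = (ay + by) / 2.0;
  double dx = ax - c.x, dy = ay - c.y;
  c.r2 = dx * dx + dy * dy;
  return c;
}

static Circ circ3(double ax, double ay, double bx, double by,
                  double cx, double cy) {
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  Circ c;
  if (std::fabs(d) < 1e-12) { // collinear: widest pair
    Circ c1 = circ2(ax, ay, bx, by), c2 = circ2(ax, ay, cx, cy),
         c3 = circ2(bx, by, cx, cy);
    c = c1;
    if (c2.r2 > c.r2) c = c2;
    if (c3.r2 > c.r2) c = c3;
    return c;
  }
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, cc2 = cx * cx + cy * cy;
  c.x = (a2 * (by - cy) + b2 * (cy - ay) + cc2 * (ay - by)) / d;
  c.y = (a2 * (cx - bx) + b2 * (ax - cx) + cc2 * (bx - ax)) / d;
  double dx = ax - c.x, dy = ay - c.y;
  c.r2 = dx * dx + dy * dy;
  return c;
}

// [[Rcpp::export(name = ".min_enclosing_circle_cpp")]]
NumericVector min_enclosing_circle_cpp(NumericMatrix pts) {
  size_t n = pts.nrow();
  if (n == 0) return NumericVector::create(0.0, 0.0, 0.0);
  std::vector<std::pair<double, double> > P(n);
  for (size_t i = 0; i < n; ++i)
    P[i] = std::make_pair(pts(i, 0), pts(i, 1));
  // deterministic LCG shuffle for expected-linear behaviour (iterative
  // Welzl / move-to-front)
  unsigned long st = 88172645463325252UL;
  for (size_t i = n; i > 1; --i) {
    st = st * 6364136223846793005UL + 1442695040888963407UL;
    size_t j = (size_t)((st >> 16) % i);
    std::swap(P[i - 1], P[j]);
  }
  Circ c; c.x = P[0].first; c.y = P[0].second; c.r2 = 0;
  for (size_t i = 1; i < n; ++i) {
    if (in_circ(c, P[i].first, P[i].second)) continue;
    c.x = P[i].first; c.y = P[i].second; c.r2 = 0;
    for (size_t j = 0; j < i; ++j) {
      if (in_circ(c, P[j].first, P[j].second)) continue;
      c = circ2(P[i].first, P[i].second, P[j].first, P[j].second);
      for (size_t k = 0; k < j; ++k) {
        if (in_circ(c, P[k].first, P[k].second)) continue;
        c = circ3(P[i].first, P[i].second, P[j].first, P[j].second,
                  P[k].first, P[k].second);
      }
    }
  }
  return NumericVector::create(c.x, c.y, std::sqrt(std::max(c.r2, 0.0)));
}

// ---- prominence-filtered local maxima (persistence / union-find) ----------

static int uf_find(std::vector<int>& par, int i) {
  while (par[i] != i) { par[i] = par[par[i]]; i = par[i]; }
  return i;
}

// Maxima of v within region whose prominence (height above the highest
// saddle to a dominating maximum) strictly exceeds tol. Plateau maxima are
// reduced to the plateau centroid snapped to the nearest plateau pixel.
// Returns m x 2 matrix of 0-based (x, y).
// [[Rcpp::export(name = ".local_maxima_prominence_cpp")]]
IntegerMatrix local_maxima_prominence_cpp(NumericMatrix v, LogicalMatrix region,
                                          double tol) {
  int H = v.nrow(), W = v.ncol();
  long N = (long)H * W;
  std::vector<long> order;
  order.reserve(1024);
  double vmin = R_PosInf;
  for (long i = 0; i < N; ++i) {
    int x = (int)(i / H), y = (int)(i % H); // column-major linear index
    if (region(y, x)) {
      order.push_back(i);
      if (v(y, x) < vmin) vmin = v(y, x);
    }
  }
  if (order.empty()) return IntegerMatrix(0, 2);
  std::stable_sort(order.begin(), order.end(), [&](long a, long b) {
    double va = v((int)(a % H), (int)(a / H)), vb = v((int)(b % H), (int)(b / H));
    if (va != vb) return va > vb;
    return a < b;
  });
  std::vector<int> par(N, -1);
  std::vector<double> peakv(N, 0.0);
  std::vector<std::vector<long> > plateau(N);
  std::vector<char> processed(N, 0);
  std::vector<std::pair<double, double> > markers;
  const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};

  std::vector<long> roots_closed; // roots that emitted markers already
  auto emit = [&](int root) {
    // centroid of the plateau, snapped to nearest plateau pixel
    double cx = 0, cy = 0;
    for (long p : plateau[root]) { cx += p / H; cy += p % H; }
    cx /= plateau[root].size(); cy /= plateau[root].size();
    double best = R_PosInf; long bp = plateau[root][0];
    for (long p : plateau[root]) {
      double ddx = p / H - cx, ddy = p % H - cy;
      double d2 = ddx * ddx + ddy * ddy;
      if (d2 < best - 1e-12 || (std::fabs(d2 - best) <= 1e-12 && p < bp)) {
        best = d2; bp = p;
      }
    }
    markers.push_back(std::make_pair((double)(bp / H), (double)(bp % H)));
  };

  for (long idx : order) {
    int x = (int)(idx / H), y = (int)(idx % H);
    double vp = v(y, x);
    std::vector<int> roots;
    for (int d = 0; d < 8; ++d) {
      int xx = x + dx8[d], yy = y + dy8[d];
      if (xx < 0 || xx >= W || yy < 0 || yy >= H) continue;
      long ni = (long)xx * H + yy;
      if (!processed[ni]) continue;
      int r = uf_find(par, (int)ni);
      if (std::find(roots.begin(), roots.end(), r) == roots.end())
        roots.push_back(r);
    }
    processed[idx] = 1;
    if (roots.empty()) {
      par[idx] = (int)idx;
      peakv[idx] = vp;
      plateau[idx].push_back(idx);
      continue;
    }
    // winner: highest peak; ties -> smaller first-plateau index
    int w = roots[0];
    for (size_t i = 1; i < roots.size(); ++i) {
      int r = roots[i];
      if (peakv[r] > peakv[w] ||
          (peakv[r] == peakv[w] && plateau[r][0] < plateau[w][0]))
        w = r;
    }
    for (int r : roots) {
      if (r == w) continue;
      double prom = peakv[r] - vp;
      if (prom > tol) {
        emit(r);
      } else if (peakv[r] == peakv[w] && vp == peakv[r]) {
        // same-level plateau components joining through a plateau pixel
        for (long p : plateau[r]) plateau[w].push_back(p);
      }
      par[r] = w;
    }
    par[idx] = w;
    if (vp == peakv[w]) plateau[w].push_back(idx);
  }
  // surviving roots: prominence relative to the region minimum
  std::vector<int> seen;
  for (long idx : order) {
    int r = uf_find(par, (int)idx);
    if (std::find(seen.begin(), seen.end(), r) == seen.end()) {
      seen.push_back(r);
      if (peakv[r] - vmin > tol) emit(r);
    }
  }
  // deterministic output order: by (x, y)
  std::sort(markers.begin(), markers.end());
  IntegerMatrix out(markers.size(), 2);
  for (size_t i = 0; i < markers.size(); ++i) {
    out(i, 0) = (int)markers[i].first;
    out(i, 1) = (int)markers[i].second;
  }
  return out;
}

// ---- marker-based watershed (priority flood) ------------------------------

// Floods the gray relief upward from markers, restricted to region.
// markers: k x 2 (x, y). Returns label matrix (0 outside/unclaimed,
// 1..k per marker).
// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerMatrix watershed_cpp(NumericMatrix relief, LogicalMatrix region,
                            IntegerMatrix markers) {
  int H = relief.nrow(), W = relief.ncol(), k = markers.nrow();
  IntegerMatrix lab(H, W);
  typedef std::tuple<double, long, long> Node; // (value, order, linear idx)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  long counter = 0;
  for (int i = 0; i < k; ++i) {
    int x = markers(i, 0), y = markers(i, 1);
    if (x < 0 || x >= W || y < 0 || y >= H || !region(y, x)) continue;
    lab(y, x) = i + 1;
    pq.push(Node(relief(y, x), counter++, (long)x * H + y));
  }
  const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    long li = std::get<2>(nd);
    int x = (int)(li / H), y = (int)(li % H);
    int l = lab(y, x);
    for (int d = 0; d < 8; ++d) {
      int xx = x + dx8[d], yy = y + dy8[d];
      if (xx < 0 || xx >= W || yy < 0 || yy >= H) continue;
      if (!region(yy, xx) || lab(yy, xx)) continue;
      lab(yy, xx) = l;
      pq.push(Node(relief(yy, xx), counter++, (long)xx * H + yy));
    }
  }
  return lab;
}

// Bilinear resize of one channel (values preserved, align-corners style
// pixel-center mapping).
// [[Rcpp::export(name = ".bilinear_resize_cpp")]]
NumericMatrix bilinear_resize_cpp(NumericMatrix img, int out_h, int out_w) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int y = 0; y < out_h; ++y) {
    double fy = (y + 0.5) * sy - 0.5;
    int y0 = (int)std::floor(fy);
    double wy = fy - y0;
    int y0c = clampi(y0, 0, H - 1), y1c = clampi(y0 + 1, 0, H - 1);
    for (int x = 0; x < out_w; ++x) {
      double fx = (x + 0.5) * sx - 0.5;
      int x0 = (int)std::floor(fx);
      double wx = fx - x0;
      int x0c = clampi(x0, 0, W - 1), x1c = clampi(x0 + 1, 0, W - 1);
      out(y, x) = (1 - wy) * ((1 - wx) * img(y0c, x0c) + wx * img(y0c, x1c)) +
                  wy * ((1 - wx) * img(y1c, x0c) + wx * img(y1c, x1c));
    }
  }
  return out;
}
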