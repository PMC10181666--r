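// Compiled geometry kernels: brute-force kNN statistics, farthest point
// sampling, flat-kernel mean-shift iteration, the greedy midrib walk,
// moving-least-squares projection, and a Bowyer-Watson planar Delaunay
// triangulation.  Clouds here are small (10^3..10^4 points), so O(n^2)
// neighbour scans are deliberate: they are exact, allocation-light and
// fast enough at this scale.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double dist2_row(const arma::mat& X, int i, int j) {
  double dx = X(i, 0) - X(j, 0);
  double dy = X(i, 1) - X(j, 1);
  double dz = X(i, 2) - X(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

// mean Euclidean distance from each point to its k nearest neighbours
// (self excluded)
// [[Rcpp::export]]
arma::vec cpp_mean_knn_dist(const arma::mat& X, int k) {
  const int n = X.n_rows;
  arma::vec out(n);
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) d[j] = dist2_row(X, i, j);
    d[i] = std::numeric_limits<double>::infinity();
    std::nth_element(d.begin(), d.begin() + (k - 1), d.end());
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += std::sqrt(d[j]);
    // nth_element leaves the k smallest in the first k slots
    out(i) = s / k;
  }
  return out;
}

// farthest point sampling: start index given (0-based), returns m 0-based
// indices in selection order
// [[Rcpp::export]]
IntegerVector cpp_fps(const arma::mat& X, int m, int start) {
  const int n = X.n_rows;
  IntegerVector sel(m);
  arma::vec mind(n);
  mind.fill(std::numeric_limits<double>::infinity());
  int cur = start;
  sel[0] = cur;
  for (int it = 1; it < m; ++it) {
    int best = -1;
    double bestd = -1.0;
    for (int j = 0; j < n; ++j) {
      double d2 = dist2_row(X, cur, j);
      if (d2 < mind(j)) mind(j) = d2;
      if (mind(j) > bestd) { bestd = mind(j); best = j; }
    }
    sel[it] = best;
    cur = best;
  }
  return sel;
}

// index (0-based) of the nearest row of X for each row of Q
// [[Rcpp::export]]
IntegerVector cpp_nn1(const arma::mat& X, const arma::mat& Q) {
  const int n = X.n_rows, q = Q.n_rows;
  IntegerVector out(q);
  for (int i = 0; i < q; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bi = 0;
    for (int j = 0; j < n; ++j) {
      double dx = Q(i, 0) - X(j, 0);
      double dy = Q(i, 1) - X(j, 1);
      double dz = Q(i, 2) - X(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bi = j; }
    }
    out[i] = bi;
  }
  return out;
}

// flat-kernel mean shift: each seed iterates to the centroid of the points
// within `radius` until displacement < tol.  Seeds whose neighbourhood is
// empty are returned as NaN rows.
// [[Rcpp::export]]
arma::mat cpp_mean_shift(const arma::mat& X, const arma::mat& seeds,
                         double radius, int max_iter, double tol) {
  const int n = X.n_rows, s = seeds.n_rows;
  const double r2 = radius * radius, tol2 = tol * tol;
  arma::mat modes(s, 3);
  for (int i = 0; i < s; ++i) {
    double cx = seeds(i, 0), cy = seeds(i, 1), cz = seeds(i, 2);
    bool ok = true;
    for (int it = 0; it < max_iter; ++it) {
      double sx = 0, sy = 0, sz = 0;
      int cnt = 0;
      for (int j = 0; j < n; ++j) {
        double dx = X(j, 0) - cx, dy = X(j, 1) - cy, dz = X(j, 2) - cz;
        if (dx * dx + dy * dy + dz * dz <= r2) {
          sx += X(j, 0); sy += X(j, 1); sz += X(j, 2); ++cnt;
        }
      }
      if (cnt == 0) { ok = false; break; }
      sx /= cnt; sy /= cnt; sz /= cnt;
      double mx = sx - cx, my = sy - cy, mz = sz - cz;
      cx = sx; cy = sy; cz = sz;
      if (mx * mx + my * my + mz * mz < tol2) break;
    }
    if (ok) { modes(i, 0) = cx; modes(i, 1) = cy; modes(i, 2) = cz; }
    else modes.row(i).fill(NA_REAL);
  }
  return modes;
}

// number of points of X within `radius` of each row of C
// [[Rcpp::export]]
IntegerVector cpp_radius_count(const arma::mat& X, const arma::mat& C,
                               double radius) {
  const int n = X.n_rows, m = C.n_rows;
  const double r2 = radius * radius;
  IntegerVector out(m);
  for (int i = 0; i < m; ++i) {
    int cnt = 0;
    for (int j = 0; j < n; ++j) {
      double dx = X(j, 0) - C(i, 0);
      double dy = X(j, 1) - C(i, 1);
      double dz = X(j, 2) - C(i, 2);
      if (dx * dx + dy * dy + dz * dz <= r2) ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}

static inline bool lex_less_pt(const arma::mat& X, int a, int b) {
  if (X(a, 0) != X(b, 0)) return X(a, 0) < X(b, 0);
  if (X(a, 1) != X(b, 1)) return X(a, 1) < X(b, 1);
  return X(a, 2) < X(b, 2);
}

// diameter pair by exhaustive search; ties (relative 1e-9) broken by the
// lexicographically smallest ordered coordinate pair
// [[Rcpp::export]]
IntegerVector cpp_farthest_pair(const arma::mat& X) {
  const int n = X.n_rows;
  double best = -1.0;
  int ba = 0, bb = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d2 = dist2_row(X, i, j);
      int a = lex_less_pt(X, i, j) ? i : j;
      int b = (a == i) ? j : i;
      if (d2 > best * (1.0 + 1e-9)) {
        best = d2; ba = a; bb = b;
      } else if (d2 > best * (1.0 - 1e-9)) {
        // tie: keep the lexicographically smaller (first, then second) pair
        bool take = false;
        if (lex_less_pt(X, a, ba)) take = true;
        else if (!lex_less_pt(X, ba, a) && lex_less_pt(X, b, bb)) take = true;
        if (take) { best = std::max(best, d2); ba = a; bb = b; }
      }
    }
  }
  return IntegerVector::create(ba, bb);
}

// Greedy midrib walk.  From `start`, repeatedly examine the k nearest
// still-available points of the current base b and move to the one
// minimising ||n-b|| + ||n-e||; the chosen point leaves the available set
// (the endpoint never does), so the walk terminates in <= n steps.
// Ties broken by smaller index.  Returns the ordered 0-based path.
// [[Rcpp::export]]
IntegerVector cpp_midrib_walk(const arma::mat& X, int start, int end, int k) {
  const int n = X.n_rows;
  std::vector<bool> avail(n, true);
  std::vector<int> path;
  path.reserve(n);
  int b = start;
  avail[start] = false;
  path.push_back(start);
  if (start == end) return wrap(path);
  std::vector<std::pair<double, int> > cand;
  cand.reserve(n);
  while (b != end) {
    cand.clear();
    for (int j = 0; j < n; ++j)
      if (avail[j]) cand.push_back(std::make_pair(dist2_row(X, b, j), j));
    if (cand.empty()) stop("midrib walk exhausted before reaching the endpoint");
    int kk = std::min((int)cand.size(), k);
    std::partial_sort(cand.begin(), cand.begin() + kk, cand.end());
    // endpoint always stays a candidate so the walk cannot stall
    bool has_end = false;
    for (int t = 0; t < kk; ++t) if (cand[t].second == end) has_end = true;
    double bestD = std::numeric_limits<double>::infinity();
    int bestj = -1;
    for (int t = 0; t < kk; ++t) {
      int j = cand[t].second;
      double ex = X(j, 0) - X(end, 0);
      double ey = X(j, 1) - X(end, 1);
      double ez = X(j, 2) - X(end, 2);
      double D = std::sqrt(cand[t].first) +
                 std::sqrt(ex * ex + ey * ey + ez * ez);
      if (D < bestD || (D == bestD && j < bestj)) { bestD = D; bestj = j; }
    }
    (void)has_end;
    path.push_back(bestj);
    if (bestj != end) avail[bestj] = false;
    b = bestj;
  }
  return wrap(path);
}

// Moving-least-squares projection.  For each point: neighbours within
// `radius`, local frame from the weighted covariance, bivariate polynomial
// fit (order 1 or 2) of the height with Gaussian weights (h = radius, the
// PCL convention), then the point is replaced by its projection onto the
// fitted surface.  Points with too few neighbours pass through untouched
// (flagged FALSE).
// [[Rcpp::export]]
List cpp_mls_smooth(const arma::mat& X, double radius, int order) {
  const int n = X.n_rows;
  const double r2 = radius * radius;
  const double h2 = radius * radius;
  const int nb = (order >= 2) ? 6 : 3;
  const int min_support = nb + 2;
  arma::mat out = X;
  LogicalVector flag(n, true);
  std::vector<int> idx;
  idx.reserve(256);
  for (int i = 0; i < n; ++i) {
    idx.clear();
    for (int j = 0; j < n; ++j)
      if (dist2_row(X, i, j) <= r2) idx.push_back(j);
    const int m = (int)idx.size();
    if (m < min_support) { flag[i] = false; continue; }
    arma::mat P(m, 3);
    arma::vec w(m);
    for (int t = 0; t < m; ++t) {
      P.row(t) = X.row(idx[t]);
      w(t) = std::exp(-dist2_row(X, i, idx[t]) / h2);
    }
    arma::rowvec mu = (w.t() * P) / arma::accu(w);
    arma::mat Pc = P.each_row() - mu;
    arma::mat C = Pc.t() * (Pc.each_col() % w);
    arma::vec eval;
    arma::mat evec;
    if (!arma::eig_sym(eval, evec, C)) { flag[i] = false; continue; }
    arma::vec nrm = evec.col(0);           // smallest eigenvalue -> normal
    arma::vec e1 = evec.col(2), e2 = evec.col(1);
    arma::vec u = Pc * e1, v = Pc * e2, ht = Pc * nrm;
    arma::mat B(m, nb);
    for (int t = 0; t < m; ++t) {
      B(t, 0) = 1.0; B(t, 1) = u(t); B(t, 2) = v(t);
      if (nb == 6) {
        B(t, 3) = u(t) * u(t); B(t, 4) = u(t) * v(t); B(t, 5) = v(t) * v(t);
      }
    }
    arma::mat Bw = B.each_col() % w;
    arma::mat A = Bw.t() * B;
    arma::vec rhs = Bw.t() * ht;
    arma::vec coef;
    if (!arma::solve(coef, A, rhs, arma::solve_opts::no_approx)) {
      flag[i] = false;
      continue;
    }
    arma::rowvec xc = X.row(i) - mu;
    double ui = arma::dot(xc, e1), vi = arma::dot(xc, e2);
    double hi = coef(0) + coef(1) * ui + coef(2) * vi;
    if (nb == 6) hi += coef(3) * ui * ui + coef(4) * ui * vi + coef(5) * vi * vi;
    arma::rowvec np = mu + ui * e1.t() + vi * e2.t() + hi * nrm.t();
    out.row(i) = np;
  }
  return List::create(_["points"] = out, _["smoothed"] = flag);
}

// ---- Bowyer-Watson Delaunay triangulation in the plane -------------------

struct DTri {
  int a, b, c;
  double cx, cy, r2;
  bool alive;
};

static bool circumcircle(const std::vector<double>& px,
                         const std::vector<double>& py,
                         int a, int b, int c, DTri& t) {
  double ax = px[a], ay = py[a], bx = px[b], by = py[b], cx = px[c], cy = py[c];
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-300) return false;
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  double ux = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  double uy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  t.a = a; t.b = b; t.c = c;
  t.cx = ux; t.cy = uy;
  double dx = ax - ux, dy = ay - uy;
  t.r2 = dx * dx + dy * dy;
  t.alive = true;
  return true;
}

// Delaunay triangulation of 2-D points (rows of P, assumed distinct).
// Returns a t x 3 matrix of 0-based vertex indices.  Cocircular point sets
// (regular grids) yield a valid, possibly non-unique, triangulation.
// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(const arma::mat& P) {
  const int n = P.n_rows;
  if (n < 3) stop("need at least 3 points to triangulate");
  // scale into [0,1]^2 for numerical stability
  double xmin = P.col(0).min(), xmax = P.col(0).max();
  double ymin = P.col(1).min(), ymax = P.col(1).max();
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) stop("degenerate (collinear or coincident) points");
  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) {
    px[i] = (P(i, 0) - xmin) / span;
    py[i] = (P(i, 1) - ymin) / span;
  }
  // super-triangle well outside the unit box
  px[n] = -10.0;  py[n] = -10.0;
  px[n + 1] = 30.0; py[n + 1] = -10.0;
  px[n + 2] = 0.5; py[n + 2] = 30.0;
  std::vector<DTri> tris;
  tris.reserve(4 * n);
  DTri t0;
  circumcircle(px, py, n, n + 1, n + 2, t0);
  tris.push_back(t0);
  const double eps = 1e-12;
  std::vector<int> bad;
  typedef std::pair<int, int> Edge;
  std::map<Edge, int> ecount;
  for (int i = 0; i < n; ++i) {
    bad.clear();
    ecount.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      double dx = px[i] - tris[t].cx, dy = py[i] - tris[t].cy;
      if (dx * dx + dy * dy < tris[t].r2 - eps) bad.push_back((int)t);
    }
    if (bad.empty()) stop("Delaunay insertion failed (duplicate point?)");
    for (size_t k = 0; k < bad.size(); ++k) {
      DTri& t = tris[bad[k]];
      int vv[3] = { t.a, t.b, t.c };
      for (int e = 0; e < 3; ++e) {
        int u = vv[e], v = vv[(e + 1) % 3];
        Edge key(std::min(u, v), std::max(u, v));
        ecount[key] += 1;
      }
      t.alive = false;
    }
    for (std::map<Edge, int>::iterator it = ecount.begin();
         it != ecount.end(); ++it) {
      if (it->second != 1) continue;     // interior edge of the cavity
      DTri nt;
      if (circumcircle(px, py, it->first.first, it->first.second, i, nt))
        tris.push_back(nt);
    }
  }
  std::vector<int> keep;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (!tris[t].alive) continue;
    if (tris[t].a >= n || tris[t].b >= n || tris[t].c >= n) continue;
    keep.push_back((int)t);
  }
  IntegerMatrix out((int)keep.size(), 3);
  for (size_t r = 0; r < keep.size(); ++r) {
    out(r, 0) = tris[keep[r]].a;
    out(r, 1) = tris[keep[r]].b;
    out(r, 2) = tris[keep[r]].c;
  }
  return out;
}
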