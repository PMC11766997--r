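// Spatial kernels: kd-tree index, radius neighbour counting, DBSCAN
// cluster expansion and RANSAC plane scoring. These are the only hot
// loops in the pipeline; everything else stays in R.

#include <Rcpp.h>
#include <algorithm>
#include <deque>
#include <vector>

using namespace Rcpp;

// kd-tree over an n x 3 coordinate matrix. Split axes cycle X -> Y -> Z
// with depth; the tree is stored implicitly as a permutation of point
// indices with the median of each range at its centre.
class KdTree3 {
public:
  int n;
  std::vector<double> px, py, pz;
  std::vector<int> perm;

  explicit KdTree3(const NumericMatrix& m) {
    n = m.nrow();
    px.resize(n); py.resize(n); pz.resize(n); perm.resize(n);
    for (int i = 0; i < n; ++i) {
      px[i] = m(i, 0); py[i] = m(i, 1); pz[i] = m(i, 2); perm[i] = i;
    }
    if (n > 1) build(0, n, 0);
  }

  double coord(int i, int ax) const {
    return ax == 0 ? px[i] : (ax == 1 ? py[i] : pz[i]);
  }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    int ax = depth % 3;
    std::nth_element(perm.begin() + lo, perm.begin() + mid, perm.begin() + hi,
                     [&](int a, int b) { return coord(a, ax) < coord(b, ax); });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  // closed axis-aligned box query: bmin <= p <= bmax on every axis
  void box_query(int lo, int hi, int depth, const double* bmin,
                 const double* bmax, std::vector<int>& out) const {
    if (lo >= hi) return;
    int mid = (lo + hi) / 2;
    int ax = depth % 3;
    int i = perm[mid];
    if (px[i] >= bmin[0] && px[i] <= bmax[0] &&
        py[i] >= bmin[1] && py[i] <= bmax[1] &&
        pz[i] >= bmin[2] && pz[i] <= bmax[2])
      out.push_back(i);
    double v = coord(i, ax);
    if (bmin[ax] <= v) box_query(lo, mid, depth + 1, bmin, bmax, out);
    if (bmax[ax] >= v) box_query(mid + 1, hi, depth + 1, bmin, bmax, out);
  }

  void radius_query(int lo, int hi, int depth, double qx, double qy, double qz,
                    double r, double r2, std::vector<int>& out) const {
    if (lo >= hi) return;
    int mid = (lo + hi) / 2;
    int ax = depth % 3;
    int i = perm[mid];
    double dx = px[i] - qx, dy = py[i] - qy, dz = pz[i] - qz;
    if (dx * dx + dy * dy + dz * dz <= r2) out.push_back(i);
    double v = coord(i, ax);
    double q = ax == 0 ? qx : (ax == 1 ? qy : qz);
    if (q - r <= v) radius_query(lo, mid, depth + 1, qx, qy, qz, r, r2, out);
    if (q + r >= v) radius_query(mid + 1, hi, depth + 1, qx, qy, qz, r, r2, out);
  }

  int radius_count(int lo, int hi, int depth, double qx, double qy, double qz,
                   double r, double r2) const {
    if (lo >= hi) return 0;
    int mid = (lo + hi) / 2;
    int ax = depth % 3;
    int i = perm[mid];
    double dx = px[i] - qx, dy = py[i] - qy, dz = pz[i] - qz;
    int cnt = (dx * dx + dy * dy + dz * dz <= r2) ? 1 : 0;
    double v = coord(i, ax);
    double q = ax == 0 ? qx : (ax == 1 ? qy : qz);
    if (q - r <= v)
      cnt += radius_count(lo, mid, depth + 1, qx, qy, qz, r, r2);
    if (q + r >= v)
      cnt += radius_count(mid + 1, hi, depth + 1, qx, qy, qz, r, r2);
    return cnt;
  }
};

// [[Rcpp::export(name = ".kd_build")]]
SEXP kd_build(NumericMatrix pts) {
  XPtr<KdTree3> p(new KdTree3(pts), true);
  return p;
}

// [[Rcpp::export(name = ".kd_size")]]
int kd_size(SEXP tree) {
  XPtr<KdTree3> p(tree);
  return p->n;
}

// [[Rcpp::export(name = ".kd_box_query")]]
IntegerVector kd_box_query(SEXP tree, NumericVector bmin, NumericVector bmax) {
  XPtr<KdTree3> p(tree);
  std::vector<int> out;
  double lo[3] = {bmin[0], bmin[1], bmin[2]};
  double hi[3] = {bmax[0], bmax[1], bmax[2]};
  p->box_query(0, p->n, 0, lo, hi, out);
  std::sort(out.begin(), out.end());
  IntegerVector res(out.size());
  for (size_t k = 0; k < out.size(); ++k) res[k] = out[k] + 1;
  return res;
}

// [[Rcpp::export(name = ".kd_radius_query")]]
IntegerVector kd_radius_query(SEXP tree, NumericVector q, double radius) {
  XPtr<KdTree3> p(tree);
  std::vector<int> out;
  p->radius_query(0, p->n, 0, q[0], q[1], q[2], radius, radius * radius, out);
  std::sort(out.begin(), out.end());
  IntegerVector res(out.size());
  for (size_t k = 0; k < out.size(); ++k) res[k] = out[k] + 1;
  return res;
}

// Number of OTHER points within `radius` of every point (self excluded).
// [[Rcpp::export(name = ".kd_neighbor_counts")]]
IntegerVector kd_neighbor_counts(NumericMatrix pts, double radius) {
  KdTree3 T(pts);
  int n = pts.nrow();
  double r2 = radius * radius;
  IntegerVector counts(n);
  for (int i = 0; i < n; ++i) {
    // self is always within its own radius, so subtract it
    counts[i] =
        T.radius_count(0, n, 0, T.px[i], T.py[i], T.pz[i], radius, r2) - 1;
  }
  return counts;
}

// Uniform grid over 3D points with cell edge = eps; eps-neighbourhood
// candidates live in the 27 surrounding cells. Used by DBSCAN, where
// every query shares the same radius, so the grid beats the kd-tree's
// log-depth traversal.
class EpsGrid {
public:
  double eps, e2;
  double ox, oy, oz;
  int nx, ny, nz;
  std::vector<double> px, py, pz;
  std::vector<std::vector<int> > cells;

  EpsGrid(const NumericMatrix& m, double eps_) : eps(eps_), e2(eps_ * eps_) {
    int n = m.nrow();
    px.resize(n); py.resize(n); pz.resize(n);
    double mx = R_PosInf, Mx = R_NegInf, my = R_PosInf, My = R_NegInf,
           mz = R_PosInf, Mz = R_NegInf;
    for (int i = 0; i < n; ++i) {
      px[i] = m(i, 0); py[i] = m(i, 1); pz[i] = m(i, 2);
      mx = std::min(mx, px[i]); Mx = std::max(Mx, px[i]);
      my = std::min(my, py[i]); My = std::max(My, py[i]);
      mz = std::min(mz, pz[i]); Mz = std::max(Mz, pz[i]);
    }
    ox = mx; oy = my; oz = mz;
    nx = (int)std::floor((Mx - mx) / eps) + 1;
    ny = (int)std::floor((My - my) / eps) + 1;
    nz = (int)std::floor((Mz - mz) / eps) + 1;
    cells.resize((size_t)nx * ny * nz);
    for (int i = 0; i < n; ++i) cells[cell_of(i)].push_back(i);
  }

  size_t cell_of(int i) const {
    int cx = (int)std::floor((px[i] - ox) / eps);
    int cy = (int)std::floor((py[i] - oy) / eps);
    int cz = (int)std::floor((pz[i] - oz) / eps);
    return ((size_t)cz * ny + cy) * nx + cx;
  }

  void neighbors(int i, std::vector<int>& out) const {
    out.clear();
    int cx = (int)std::floor((px[i] - ox) / eps);
    int cy = (int)std::floor((py[i] - oy) / eps);
    int cz = (int)std::floor((pz[i] - oz) / eps);
    for (int dz = -1; dz <= 1; ++dz) {
      int z = cz + dz;
      if (z < 0 || z >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int y = cy + dy;
        if (y < 0 || y >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int x = cx + dx;
          if (x < 0 || x >= nx) continue;
          const std::vector<int>& c = cells[((size_t)z * ny + y) * nx + x];
          for (int j : c) {
            double ax = px[j] - px[i], ay = py[j] - py[i], az = pz[j] - pz[i];
            if (ax * ax + ay * ay + az * az <= e2) out.push_back(j);
          }
        }
      }
    }
    std::sort(out.begin(), out.end());
  }
};

// DBSCAN with self-inclusive core test. Points are visited in index
// order and each neighbour list is scanned in sorted index order, so a
// border point reachable from two clusters joins the first-visited one.
// Labels: -1 = noise, clusters numbered 1.. in order of discovery.
// [[Rcpp::export(name = ".dbscan_labels")]]
IntegerVector dbscan_labels(NumericMatrix pts, double eps, int min_pts) {
  EpsGrid G(pts, eps);
  int n = pts.nrow();
  IntegerVector label(n, 0); // 0 = unvisited
  int cid = 0;
  std::vector<int> nb, nb2;
  for (int i = 0; i < n; ++i) {
    if (label[i] != 0) continue;
    G.neighbors(i, nb);
    if ((int)nb.size() < min_pts) {
      label[i] = -1; // provisionally noise; may become a border point
      continue;
    }
    ++cid;
    label[i] = cid;
    std::deque<int> seeds(nb.begin(), nb.end());
    while (!seeds.empty()) {
      int q = seeds.front();
      seeds.pop_front();
      if (label[q] == cid) continue;
      if (label[q] > 0) continue;    // already claimed by an earlier cluster
      bool was_noise = (label[q] == -1);
      label[q] = cid;
      if (was_noise) continue;       // noise -> border point, do not expand
      G.neighbors(q, nb2);
      if ((int)nb2.size() >= min_pts) {
        for (int j : nb2)
          if (label[j] <= 0) seeds.push_back(j);
      }
    }
  }
  return label;
}

// Mean distance from every point to its k nearest OTHER points,
// computed with a bounded max-heap over an expanding kd radius search.
// [[Rcpp::export(name = ".kd_knn_mean_dist")]]
NumericVector kd_knn_mean_dist(NumericMatrix pts, int k) {
  KdTree3 T(pts);
  int n = pts.nrow();
  NumericVector out(n);
  if (n <= 1) return out;
  if (k > n - 1) k = n - 1;
  // seed search radius from the bounding-box density estimate
  double vol = 1.0;
  for (int a = 0; a < 3; ++a) {
    double mn = R_PosInf, mx = R_NegInf;
    for (int i = 0; i < n; ++i) {
      double v = a == 0 ? T.px[i] : (a == 1 ? T.py[i] : T.pz[i]);
      mn = std::min(mn, v); mx = std::max(mx, v);
    }
    if (mx > mn) vol *= (mx - mn);
  }
  double r0 = std::cbrt(vol * (k + 1) / std::max(1, n)) + 1e-9;
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    double r = r0;
    for (;;) {
      nb.clear();
      T.radius_query(0, n, 0, T.px[i], T.py[i], T.pz[i], r, r * r, nb);
      if ((int)nb.size() >= k + 1) break; // self included
      r *= 2.0;
    }
    std::vector<double> d;
    d.reserve(nb.size());
    for (int j : nb) {
      if (j == i) continue;
      double dx = T.px[j] - T.px[i], dy = T.py[j] - T.py[i],
             dz = T.pz[j] - T.pz[i];
      d.push_back(std::sqrt(dx * dx + dy * dy + dz * dz));
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    double s = 0;
    for (int j = 0; j < k; ++j) s += d[j];
    out[i] = s / k;
  }
  return out;
}

// Score pre-drawn RANSAC minimal samples. `samples` holds 1-based point
// index triplets (one row per iteration, drawn in R so the RNG stream is
// R's). Returns the plane with the most inliers; ties keep the earliest
// iteration. Degenerate (collinear) samples are skipped.
// [[Rcpp::export(name = ".ransac_plane_score")]]
List ransac_plane_score(NumericMatrix pts, IntegerMatrix samples,
                        double threshold) {
  int n = pts.nrow(), m = samples.nrow();
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2); }
  int best_count = -1, best_iter = -1;
  double bn[3] = {0, 0, 0}, bd = 0;
  for (int s = 0; s < m; ++s) {
    int i1 = samples(s, 0) - 1, i2 = samples(s, 1) - 1, i3 = samples(s, 2) - 1;
    double ux = X[i2] - X[i1], uy = Y[i2] - Y[i1], uz = Z[i2] - Z[i1];
    double vx = X[i3] - X[i1], vy = Y[i3] - Y[i1], vz = Z[i3] - Z[i1];
    double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz,
           nz = ux * vy - uy * vx;
    double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (nn < 1e-12) continue; // collinear sample
    nx /= nn; ny /= nn; nz /= nn;
    double d = -(nx * X[i1] + ny * Y[i1] + nz * Z[i1]);
    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      double dist = nx * X[i] + ny * Y[i] + nz * Z[i] + d;
      if (dist < 0) dist = -dist;
      if (dist <= threshold) ++cnt;
    }
    if (cnt > best_count) {
      best_count = cnt;
      best_iter = s + 1;
      bn[0] = nx; bn[1] = ny; bn[2] = nz; bd = d;
    }
  }
  if (best_count < 0)
    return List::create(Named("ok") = false);
  return List::create(Named("ok") = true,
                      Named("normal") = NumericVector::create(bn[0], bn[1], bn[2]),
                      Named("offset") = bd,
                      Named("inlier_count") = best_count,
                      Named("iteration") = best_iter);
}
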