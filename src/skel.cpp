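// Compiled kernels for point-cloud skeletonization: k-nearest-neighbor
// search, the locally triangulated cotangent Laplacian, radius clustering
// and greedy adaptive sphere sampling.
#include <RcppArmadillo.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <queue>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// k-d tree (3D) for kNN queries

struct KDNode {
  int left = -1, right = -1;
  int start = 0, end = 0;  // leaf range into idx
  int axis = -1;
  double split = 0.0;
};

struct KDTree {
  const arma::mat& X;  // n x 3
  std::vector<int> idx;
  std::vector<KDNode> nodes;
  int leaf_size = 16;

  explicit KDTree(const arma::mat& X_) : X(X_) {
    int n = X.n_rows;
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    if (n > 0) build(0, n);
  }

  int build(int start, int end) {
    int id = (int)nodes.size();
    nodes.push_back(KDNode());
    nodes[id].start = start;
    nodes[id].end = end;
    if (end - start <= leaf_size) return id;
    // widest axis
    double best_w = -1.0;
    int axis = 0;
    for (int a = 0; a < 3; ++a) {
      double lo = X(idx[start], a), hi = lo;
      for (int i = start; i < end; ++i) {
        double v = X(idx[i], a);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      if (hi - lo > best_w) { best_w = hi - lo; axis = a; }
    }
    if (best_w <= 0.0) return id;  // all coincident: stay a leaf
    int mid = (start + end) / 2;
    std::nth_element(idx.begin() + start, idx.begin() + mid, idx.begin() + end,
                     [&](int a, int b) { return X(a, axis) < X(b, axis); });
    nodes[id].axis = axis;
    nodes[id].split = X(idx[mid], axis);
    int l = build(start, mid);
    int r = build(mid, end);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  // k nearest neighbors of query point q, excluding point index `self` (-1 = none)
  void knn(const double* q, int k, int self,
           std::vector<std::pair<double, int>>& heap) const {
    heap.clear();
    search(0, q, k, self, heap);
    std::sort_heap(heap.begin(), heap.end());
  }

  void search(int node, const double* q, int k, int self,
              std::vector<std::pair<double, int>>& heap) const {
    const KDNode& nd = nodes[node];
    if (nd.axis < 0) {
      for (int i = nd.start; i < nd.end; ++i) {
        int p = idx[i];
        if (p == self) continue;
        double d = 0.0;
        for (int a = 0; a < 3; ++a) {
          double t = X(p, a) - q[a];
          d += t * t;
        }
        if ((int)heap.size() < k) {
          heap.push_back({d, p});
          std::push_heap(heap.begin(), heap.end());
        } else if (d < heap.front().first) {
          std::pop_heap(heap.begin(), heap.end());
          heap.back() = {d, p};
          std::push_heap(heap.begin(), heap.end());
        }
      }
      return;
    }
    double diff = q[nd.axis] - nd.split;
    int near = diff <= 0 ? nd.left : nd.right;
    int far = diff <= 0 ? nd.right : nd.left;
    search(near, q, k, self, heap);
    if ((int)heap.size() < k || diff * diff < heap.front().first)
      search(far, q, k, self, heap);
  }

  // all points within radius r of q
  void radius(const double* q, double r, std::vector<int>& out) const {
    out.clear();
    radius_search(0, q, r * r, out);
  }

  void radius_search(int node, const double* q, double r2,
                     std::vector<int>& out) const {
    const KDNode& nd = nodes[node];
    if (nd.axis < 0) {
      for (int i = nd.start; i < nd.end; ++i) {
        int p = idx[i];
        double d = 0.0;
        for (int a = 0; a < 3; ++a) {
          double t = X(p, a) - q[a];
          d += t * t;
        }
        if (d <= r2) out.push_back(p);
      }
      return;
    }
    double diff = q[nd.axis] - nd.split;
    int near = diff <= 0 ? nd.left : nd.right;
    int far = diff <= 0 ? nd.right : nd.left;
    radius_search(near, q, r2, out);
    if (diff * diff <= r2) radius_search(far, q, r2, out);
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_knn(const arma::mat& X, int k) {
  int n = X.n_rows;
  if (k >= n) stop("k must be smaller than the number of points");
  KDTree tree(X);
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int>> heap;
  heap.reserve(k + 1);
  for (int i = 0; i < n; ++i) {
    double q[3] = {X(i, 0), X(i, 1), X(i, 2)};
    tree.knn(q, k, i, heap);
    for (int j = 0; j < k; ++j) out(i, j) = heap[j].second + 1;  // 1-based
  }
  return out;
}

// ---------------------------------------------------------------------------
// Bowyer-Watson Delaunay triangulation of a small 2D point set

struct Tri {
  int a, b, c;
  double cx, cy, r2;  // circumcircle
  bool alive = true;
};

static bool circumcircle(const std::vector<double>& px,
                         const std::vector<double>& py, int a, int b, int c,
                         double& cx, double& cy, double& r2) {
  double ax = px[a], ay = py[a], bx = px[b], by = py[b], ccx = px[c],
         ccy = py[c];
  double d = 2.0 * (ax * (by - ccy) + bx * (ccy - ay) + ccx * (ay - by));
  if (std::fabs(d) < 1e-300) return false;
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by,
         c2 = ccx * ccx + ccy * ccy;
  cx = (a2 * (by - ccy) + b2 * (ccy - ay) + c2 * (ay - by)) / d;
  cy = (a2 * (ccx - bx) + b2 * (ax - ccx) + c2 * (bx - ax)) / d;
  double dx = ax - cx, dy = ay - cy;
  r2 = dx * dx + dy * dy;
  return true;
}

// returns triangles as index triples into the input points; empty on failure
static std::vector<std::array<int, 3>> delaunay2d(std::vector<double> px,
                                                  std::vector<double> py) {
  int m = (int)px.size();
  std::vector<std::array<int, 3>> out;
  if (m < 3) return out;
  // super-triangle
  double lo_x = px[0], hi_x = px[0], lo_y = py[0], hi_y = py[0];
  for (int i = 1; i < m; ++i) {
    lo_x = std::min(lo_x, px[i]); hi_x = std::max(hi_x, px[i]);
    lo_y = std::min(lo_y, py[i]); hi_y = std::max(hi_y, py[i]);
  }
  double span = std::max(hi_x - lo_x, hi_y - lo_y);
  if (span <= 0) return out;  // all coincident
  double midx = 0.5 * (lo_x + hi_x), midy = 0.5 * (lo_y + hi_y);
  px.push_back(midx - 20 * span); py.push_back(midy - 10 * span);
  px.push_back(midx + 20 * span); py.push_back(midy - 10 * span);
  px.push_back(midx);             py.push_back(midy + 20 * span);
  std::vector<Tri> tris;
  Tri super{m, m + 1, m + 2};
  if (!circumcircle(px, py, super.a, super.b, super.c, super.cx, super.cy,
                    super.r2))
    return out;
  tris.push_back(super);
  for (int p = 0; p < m; ++p) {
    std::vector<std::pair<int, int>> edges;  // boundary of the cavity
    for (auto& t : tris) {
      if (!t.alive) continue;
      double dx = px[p] - t.cx, dy = py[p] - t.cy;
      if (dx * dx + dy * dy <= t.r2 * (1.0 + 1e-12)) {
        t.alive = false;
        edges.push_back({t.a, t.b});
        edges.push_back({t.b, t.c});
        edges.push_back({t.c, t.a});
      }
    }
    // remove doubled edges (shared between two removed triangles)
    std::vector<std::pair<int, int>> boundary;
    for (size_t i = 0; i < edges.size(); ++i) {
      bool dup = false;
      for (size_t j = 0; j < edges.size(); ++j) {
        if (i == j) continue;
        if ((edges[i].first == edges[j].second &&
             edges[i].second == edges[j].first) ||
            (edges[i].first == edges[j].first &&
             edges[i].second == edges[j].second)) {
          dup = true;
          break;
        }
      }
      if (!dup) boundary.push_back(edges[i]);
    }
    for (auto& e : boundary) {
      Tri t{e.first, e.second, p};
      if (circumcircle(px, py, t.a, t.b, t.c, t.cx, t.cy, t.r2))
        tris.push_back(t);
    }
    // compact occasionally
    if (tris.size() > 512) {
      std::vector<Tri> keep;
      for (auto& t : tris)
        if (t.alive) keep.push_back(t);
      tris.swap(keep);
    }
  }
  for (auto& t : tris) {
    if (!t.alive) continue;
    if (t.a >= m || t.b >= m || t.c >= m) continue;  // touches super-triangle
    out.push_back({t.a, t.b, t.c});
  }
  return out;
}

static double cot_at(const arma::rowvec& apex, const arma::rowvec& u,
                     const arma::rowvec& v) {
  arma::rowvec e1 = u - apex, e2 = v - apex;
  double cross = arma::norm(arma::cross(e1, e2), 2);
  double dot = arma::dot(e1, e2);
  if (cross < 1e-300) return 0.0;
  return dot / cross;
}

// Cotangent Laplacian rows from local tangent-plane Delaunay one-rings.
// NN is n x k, 1-based. Returns COO triplets of the off-diagonal entries
// (diagonal = -rowsum is added on the R side), one-ring total edge length S,
// and the count of degenerate rows that fell back to uniform weights.
// [[Rcpp::export]]
List cpp_cotan_laplacian(const arma::mat& X, const IntegerMatrix& NN,
                         double clamp) {
  int n = X.n_rows, k = NN.ncol();
  std::vector<int> ri, rj;
  std::vector<double> rw;
  ri.reserve((size_t)n * 7);
  rj.reserve((size_t)n * 7);
  rw.reserve((size_t)n * 7);
  arma::vec S(n, arma::fill::zeros);
  int fallbacks = 0;
  std::vector<double> px, py;
  for (int i = 0; i < n; ++i) {
    // local neighborhood: self first, then the k neighbors
    arma::mat P(k + 1, 3);
    std::vector<int> gid(k + 1);
    P.row(0) = X.row(i);
    gid[0] = i;
    for (int j = 0; j < k; ++j) {
      gid[j + 1] = NN(i, j) - 1;
      P.row(j + 1) = X.row(gid[j + 1]);
    }
    arma::rowvec mu = arma::mean(P, 0);
    arma::mat C = P.each_row() - mu;
    arma::mat cov = C.t() * C;
    arma::vec eigval;
    arma::mat eigvec;
    bool ok = arma::eig_sym(eigval, eigvec, cov);
    bool done = false;
    if (ok && eigval(1) > 1e-20 * std::max(1.0, eigval(2))) {
      // project on the two leading principal directions
      arma::vec e1 = eigvec.col(2), e2 = eigvec.col(1);
      px.assign(k + 1, 0.0);
      py.assign(k + 1, 0.0);
      for (int j = 0; j <= k; ++j) {
        px[j] = arma::dot(C.row(j), e1);
        py[j] = arma::dot(C.row(j), e2);
      }
      auto tris = delaunay2d(px, py);
      if (!tris.empty()) {
        // one-ring of local vertex 0
        std::unordered_map<int, double> w;     // local nbr -> weight
        for (auto& t : tris) {
          int v[3] = {t[0], t[1], t[2]};
          for (int a = 0; a < 3; ++a) {
            int p = v[a], q = v[(a + 1) % 3], o = v[(a + 2) % 3];
            if (p == 0 || q == 0) {
              int nbr = (p == 0) ? q : p;
              if (nbr == 0) continue;
              // cotangent at the corner opposite the edge (0, nbr); each
              // incident triangle contributes one term, so shared edges
              // accumulate cot(alpha) + cot(beta)
              arma::rowvec apex = X.row(gid[o]);
              arma::rowvec u = X.row(gid[p]);
              arma::rowvec v = X.row(gid[q]);
              double ct = cot_at(apex, u, v);
              ct = std::max(-clamp, std::min(clamp, ct));
              w[nbr] += ct;
            }
          }
        }
        if (!w.empty()) {
          // deterministic order
          std::vector<std::pair<int, double>> ring(w.begin(), w.end());
          std::sort(ring.begin(), ring.end());
          double s = 0.0;
          for (auto& pr : ring) {
            int g = gid[pr.first];
            ri.push_back(i);
            rj.push_back(g);
            rw.push_back(pr.second);
            s += arma::norm(X.row(i) - X.row(g), 2);
          }
          S(i) = s;
          done = true;
        }
      }
    }
    if (!done) {
      // degenerate neighborhood (exactly collinear or coincident): no
      // curvature flow is defined, so the row exerts no contraction force
      // and the point is held by its attraction term alone. This keeps
      // exactly collinear chains fixed points of the contraction.
      ++fallbacks;
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        int g = NN(i, j) - 1;
        ri.push_back(i);
        rj.push_back(g);
        rw.push_back(0.0);
        s += arma::norm(X.row(i) - X.row(g), 2);
      }
      S(i) = s;
    }
  }
  return List::create(Named("i") = wrap(ri), Named("j") = wrap(rj),
                      Named("w") = wrap(rw), Named("S") = S,
                      Named("fallbacks") = fallbacks);
}

// ---------------------------------------------------------------------------
// Wait-free helpers for denoising and sampling

// Connected components of the <= r proximity graph, by BFS over a k-d tree.
// Labels are 1-based, assigned in order of first discovery from point 1.
// [[Rcpp::export]]
IntegerVector cpp_radius_components(const arma::mat& X, double r) {
  int n = X.n_rows;
  IntegerVector lab(n, 0);
  KDTree tree(X);
  std::vector<int> nbrs;
  int comp = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (lab[s]) continue;
    ++comp;
    lab[s] = comp;
    stack.push_back(s);
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      double q[3] = {X(p, 0), X(p, 1), X(p, 2)};
      tree.radius(q, r, nbrs);
      for (int m : nbrs) {
        if (!lab[m]) {
          lab[m] = comp;
          stack.push_back(m);
        }
      }
    }
  }
  return lab;
}

// Number of points of X within radius r of each row of Q (a point of X
// located exactly at a query counts itself).
// [[Rcpp::export]]
IntegerVector cpp_radius_count(const arma::mat& X, const arma::mat& Q,
                               double r) {
  KDTree tree(X);
  int m = Q.n_rows;
  IntegerVector out(m);
  std::vector<int> nbrs;
  for (int i = 0; i < m; ++i) {
    double q[3] = {Q(i, 0), Q(i, 1), Q(i, 2)};
    tree.radius(q, r, nbrs);
    out[i] = (int)nbrs.size();
  }
  return out;
}

// Greedy adaptive sphere sampling. is_joint flags points classified as
// junction (small directionality). Seeds are chosen as the unabsorbed point
// with the most unabsorbed points within r_branch (ties: lowest index); the
// seed absorbs everything unabsorbed within its class radius. Returns the
// 1-based absorbing-seed order for every point plus the seed indices.
// [[Rcpp::export]]
List cpp_adaptive_sample(const arma::mat& X, const LogicalVector& is_joint,
                         double r_branch, double r_joint) {
  int n = X.n_rows;
  KDTree tree(X);
  // neighbor counts within r_branch
  std::vector<std::vector<int>> adj(n);
  std::vector<int> cnt(n);
  std::vector<int> nbrs;
  for (int i = 0; i < n; ++i) {
    double q[3] = {X(i, 0), X(i, 1), X(i, 2)};
    tree.radius(q, r_branch, nbrs);
    for (int m : nbrs)
      if (m != i) adj[i].push_back(m);
    cnt[i] = (int)adj[i].size();
  }
  std::vector<int> assign(n, 0);
  std::vector<int> seeds;
  int absorbed = 0;
  while (absorbed < n) {
    int best = -1, best_cnt = -1;
    for (int i = 0; i < n; ++i)
      if (!assign[i] && cnt[i] > best_cnt) { best_cnt = cnt[i]; best = i; }
    double r = is_joint[best] ? r_joint : r_branch;
    int key = (int)seeds.size() + 1;
    seeds.push_back(best + 1);
    double q[3] = {X(best, 0), X(best, 1), X(best, 2)};
    tree.radius(q, r, nbrs);
    std::vector<int> newly;
    if (!assign[best]) newly.push_back(best);
    for (int m : nbrs)
      if (!assign[m] && m != best) newly.push_back(m);
    for (int m : newly) {
      assign[m] = key;
      ++absorbed;
      for (int b : adj[m]) --cnt[b];
    }
  }
  return List::create(Named("assign") = wrap(assign),
                      Named("seeds") = wrap(seeds));
}
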