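#include <RcppArmadillo.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static std::vector<std::vector<int>> adjacency(const IntegerMatrix& F, int nv) {
  std::vector<std::vector<int>> adj(nv);
  for (int f = 0; f < F.nrow(); ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int v = 0; v < nv; ++v) {
    std::sort(adj[v].begin(), adj[v].end());
    adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
  }
  return adj;
}

// Barycentric (one-third triangle) vertex area weights.
// [[Rcpp::export(name = ".cpp_vertex_areas")]]
NumericVector cpp_vertex_areas(NumericMatrix V, IntegerMatrix F) {
  NumericVector area(V.nrow(), 0.0);
  for (int f = 0; f < F.nrow(); ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    double ux = V(b, 0) - V(a, 0), uy = V(b, 1) - V(a, 1), uz = V(b, 2) - V(a, 2);
    double vx = V(c, 0) - V(a, 0), vy = V(c, 1) - V(a, 1), vz = V(c, 2) - V(a, 2);
    double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
    double A = 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
    area[a] += A / 3.0; area[b] += A / 3.0; area[c] += A / 3.0;
  }
  return area;
}

// Area-weighted vertex normals (faces assumed consistently oriented).
// [[Rcpp::export(name = ".cpp_vertex_normals")]]
NumericMatrix cpp_vertex_normals(NumericMatrix V, IntegerMatrix F) {
  NumericMatrix N(V.nrow(), 3);
  for (int f = 0; f < F.nrow(); ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    double ux = V(b, 0) - V(a, 0), uy = V(b, 1) - V(a, 1), uz = V(b, 2) - V(a, 2);
    double vx = V(c, 0) - V(a, 0), vy = V(c, 1) - V(a, 1), vz = V(c, 2) - V(a, 2);
    double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
    for (int w : {a, b, c}) {
      N(w, 0) += cx; N(w, 1) += cy; N(w, 2) += cz;
    }
  }
  for (int v = 0; v < N.nrow(); ++v) {
    double n = std::sqrt(N(v, 0) * N(v, 0) + N(v, 1) * N(v, 1) + N(v, 2) * N(v, 2));
    if (n > 0) { N(v, 0) /= n; N(v, 1) /= n; N(v, 2) /= n; }
  }
  return N;
}

// Taubin lambda/mu smoothing with the uniform graph Laplacian. Shrink-free
// feature-preserving smoothing of the marching-tetrahedra staircase.
// [[Rcpp::export(name = ".cpp_taubin_smooth")]]
NumericMatrix cpp_taubin_smooth(NumericMatrix V, IntegerMatrix F,
                                double lambda, double mu, int iters) {
  const int nv = V.nrow();
  auto adj = adjacency(F, nv);
  NumericMatrix cur = clone(V);
  NumericMatrix nxt(nv, 3);
  for (int it = 0; it < iters; ++it) {
    for (double step : {lambda, mu}) {
      for (int v = 0; v < nv; ++v) {
        if (adj[v].empty()) {
          for (int d = 0; d < 3; ++d) nxt(v, d) = cur(v, d);
          continue;
        }
        for (int d = 0; d < 3; ++d) {
          double m = 0;
          for (int u : adj[v]) m += cur(u, d);
          m /= adj[v].size();
          nxt(v, d) = cur(v, d) + step * (m - cur(v, d));
        }
      }
      std::swap(cur, nxt);
    }
  }
  return cur;
}

// Per-vertex principal curvatures by a local quadric fit over the 2-ring
// neighborhood, in the frame of the outward vertex normal. Returns kappa1 >=
// kappa2 with the convention that a convex surface (sphere with outward
// normals) has positive curvature. Vertices with ill-conditioned fits are
// flagged unreliable.
// [[Rcpp::export(name = ".cpp_quadric_curvatures")]]
List cpp_quadric_curvatures(NumericMatrix V, IntegerMatrix F,
                            NumericMatrix N, int rings = 2) {
  const int nv = V.nrow();
  auto adj = adjacency(F, nv);
  NumericVector k1(nv, NA_REAL), k2(nv, NA_REAL);
  LogicalVector reliable(nv, false);
  std::vector<int> ring;
  std::vector<char> seen(nv, 0);

  for (int v = 0; v < nv; ++v) {
    // n-ring neighborhood
    ring.clear();
    seen[v] = 1;
    for (int u : adj[v]) if (!seen[u]) { seen[u] = 1; ring.push_back(u); }
    size_t lo = 0;
    for (int depth = 1; depth < rings; ++depth) {
      size_t hi = ring.size();
      for (size_t r = lo; r < hi; ++r)
        for (int w : adj[ring[r]])
          if (!seen[w]) { seen[w] = 1; ring.push_back(w); }
      lo = hi;
    }
    for (int u : ring) seen[u] = 0;
    seen[v] = 0;

    if (ring.size() < 5) continue;
    arma::vec n = {N(v, 0), N(v, 1), N(v, 2)};
    double nn = arma::norm(n);
    if (nn < 1e-12) continue;
    n /= nn;
    arma::vec a = (std::abs(n[0]) < 0.9) ? arma::vec({1, 0, 0})
                                         : arma::vec({0, 1, 0});
    arma::vec e1 = a - arma::dot(a, n) * n;
    e1 /= arma::norm(e1);
    arma::vec e2 = arma::cross(n, e1);

    const int m = (int)ring.size();
    arma::mat A(m, 5);
    arma::vec h(m);
    for (int r = 0; r < m; ++r) {
      arma::vec d = {V(ring[r], 0) - V(v, 0), V(ring[r], 1) - V(v, 1),
                     V(ring[r], 2) - V(v, 2)};
      double x = arma::dot(d, e1), y = arma::dot(d, e2);
      A(r, 0) = x * x; A(r, 1) = x * y; A(r, 2) = y * y;
      A(r, 3) = x;     A(r, 4) = y;
      h[r] = arma::dot(d, n);
    }
    arma::vec coef;
    bool ok = arma::solve(coef, A, h, arma::solve_opts::no_approx);
    if (!ok || !coef.is_finite()) continue;
    double ca = coef[0], cb = coef[1], cc = coef[2], cd = coef[3], ce = coef[4];
    double denom = std::sqrt(1.0 + cd * cd + ce * ce);
    // first and second fundamental forms of the Monge patch h(x, y)
    double E = 1 + cd * cd, Ff = cd * ce, G = 1 + ce * ce;
    double L = 2 * ca / denom, M = cb / denom, Nn = 2 * cc / denom;
    double detI = E * G - Ff * Ff;
    if (detI < 1e-12) continue;
    // shape operator wrt the *inward*-bending patch; negate so convex
    // surfaces with outward normals get positive curvature
    double w11 = (L * G - M * Ff) / detI;
    double w12 = (M * G - Nn * Ff) / detI;
    double w21 = (M * E - L * Ff) / detI;
    double w22 = (Nn * E - M * Ff) / detI;
    double tr = -(w11 + w22);
    double det = (w11 * w22 - w12 * w21);
    double disc = tr * tr - 4 * det;
    if (disc < 0) disc = 0;
    double s = std::sqrt(disc);
    k1[v] = (tr + s) / 2.0;
    k2[v] = (tr - s) / 2.0;
    reliable[v] = true;
  }
  return List::create(_["kappa1"] = k1, _["kappa2"] = k2,
                      _["reliable"] = reliable);
}

// For every vertex, the area mass of each class within the geodesic
// (edge-path) distance `radius`. Truncated Dijkstra per source vertex.
// classes are 1-based in 1..K; returns a K x nv matrix.
// [[Rcpp::export(name = ".cpp_geodesic_class_mass")]]
NumericMatrix cpp_geodesic_class_mass(NumericMatrix V, IntegerMatrix F,
                                      IntegerVector cls, NumericVector area,
                                      int K, double radius) {
  const int nv = V.nrow();
  auto adj = adjacency(F, nv);
  // precompute edge lengths
  std::vector<std::vector<double>> elen(nv);
  for (int v = 0; v < nv; ++v) {
    elen[v].resize(adj[v].size());
    for (size_t e = 0; e < adj[v].size(); ++e) {
      int u = adj[v][e];
      double dx = V(u, 0) - V(v, 0), dy = V(u, 1) - V(v, 1),
             dz = V(u, 2) - V(v, 2);
      elen[v][e] = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  NumericMatrix mass(K, nv);
  std::vector<double> dist(nv, -1.0);
  std::vector<char> done(nv, 0);
  std::vector<int> touched;
  typedef std::pair<double, int> QE;
  for (int s = 0; s < nv; ++s) {
    std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
    dist[s] = 0.0;
    touched.push_back(s);
    pq.push({0.0, s});
    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      double d = top.first; int v = top.second;
      if (done[v] || d > dist[v]) continue;
      done[v] = 1;
      int c = cls[v];
      if (c >= 1 && c <= K) mass(c - 1, s) += area[v];
      for (size_t e = 0; e < adj[v].size(); ++e) {
        int u = adj[v][e];
        double nd = d + elen[v][e];
        if (nd > radius) continue;
        if (dist[u] < 0 || nd < dist[u]) {
          if (dist[u] < 0) touched.push_back(u);
          dist[u] = nd;
          pq.push({nd, u});
        }
      }
    }
    for (int u : touched) { dist[u] = -1.0; done[u] = 0; }
    touched.clear();
  }
  return mass;
}

// Smooth a per-vertex scalar by repeated neighbor averaging (50/50 blend of
// self and 1-ring mean). Used to stabilize scalar fields (e.g. mean
// curvature) before using them as displacements.
// [[Rcpp::export(name = ".cpp_smooth_scalar")]]
NumericVector cpp_smooth_scalar(NumericMatrix V, IntegerMatrix F,
                                NumericVector x, int iters) {
  const int nv = V.nrow();
  auto adj = adjacency(F, nv);
  NumericVector cur = clone(x);
  NumericVector nxt(nv);
  for (int it = 0; it < iters; ++it) {
    for (int v = 0; v < nv; ++v) {
      if (adj[v].empty()) { nxt[v] = cur[v]; continue; }
      double m = 0;
      for (int u : adj[v]) m += cur[u];
      nxt[v] = 0.5 * cur[v] + 0.5 * m / adj[v].size();
    }
    std::swap(cur, nxt);
  }
  return cur;
}
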