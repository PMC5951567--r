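#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cmath>

using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra on a 6-tetrahedra cube
// decomposition. Every case is unambiguous, so the triangulation of a closed
// level set is watertight. Triangles are oriented so normals point from the
// inside region (field > iso) outwards. Vertices are welded on shared lattice
// edges and returned in world coordinates (origin + index * spacing).

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

// [[Rcpp::export(name = ".cpp_marching_tet")]]
List cpp_marching_tet(NumericVector field, IntegerVector dim,
                      NumericVector spacing, NumericVector origin,
                      double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  auto lin = [nx, ny](int i, int j, int k) { return i + nx * (j + ny * k); };

  MTState st;
  // world coordinate of lattice point
  auto wx = [&](int g) { return origin[0] + spacing[0] * (g % nx); };
  auto wy = [&](int g) { return origin[1] + spacing[1] * ((g / nx) % ny); };
  auto wz = [&](int g) { return origin[2] + spacing[2] * (g / (nx * ny)); };

  auto edge_pt = [&](int ga, int gb) -> int {
    int a = ga, b = gb;
    double fa = field[a], fb = field[b];
    if (a > b) { std::swap(a, b); std::swap(fa, fb); }
    uint64_t key = ((uint64_t)a << 32) | (uint64_t)b;
    auto it = st.edge_vertex.find(key);
    if (it != st.edge_vertex.end()) return it->second;
    double t = (iso - fa) / (fb - fa);
    // keep interpolated vertices away from lattice points: avoids
    // near-degenerate sliver triangles that destabilize curvature fits
    if (t < 0.05) t = 0.05;
    if (t > 0.95) t = 0.95;
    int id = (int)st.vx.size();
    st.edge_vertex.emplace(key, id);
    st.vx.push_back(wx(a) + t * (wx(b) - wx(a)));
    st.vy.push_back(wy(a) + t * (wy(b) - wy(a)));
    st.vz.push_back(wz(a) + t * (wz(b) - wz(a)));
    return id;
  };

  auto add_tri = [&](int p0, int p1, int p2,
                     double rx, double ry, double rz) {
    // reference direction r points from inside towards outside; orient so the
    // triangle normal agrees with it
    double ax = st.vx[p1] - st.vx[p0], ay = st.vy[p1] - st.vy[p0],
           az = st.vz[p1] - st.vz[p0];
    double bx = st.vx[p2] - st.vx[p0], by = st.vy[p2] - st.vy[p0],
           bz = st.vz[p2] - st.vz[p0];
    double nxv = ay * bz - az * by, nyv = az * bx - ax * bz,
           nzv = ax * by - ay * bx;
    if (nxv * rx + nyv * ry + nzv * rz < 0) std::swap(p1, p2);
    st.f0.push_back(p0); st.f1.push_back(p1); st.f2.push_back(p2);
  };

  // tetrahedra sharing the cube diagonal c0-c6
  static const int tets[6][4] = {
    {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
    {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        int c[8] = {lin(i, j, k),         lin(i + 1, j, k),
                    lin(i + 1, j + 1, k), lin(i, j + 1, k),
                    lin(i, j, k + 1),     lin(i + 1, j, k + 1),
                    lin(i + 1, j + 1, k + 1), lin(i, j + 1, k + 1)};
        // quick reject: all on one side
        bool any_in = false, any_out = false;
        for (int v = 0; v < 8; ++v)
          (field[c[v]] > iso ? any_in : any_out) = true;
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          int g[4];
          bool in[4];
          int nin = 0;
          for (int v = 0; v < 4; ++v) {
            g[v] = c[tets[t][v]];
            in[v] = field[g[v]] > iso;
            if (in[v]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          // centroid difference (outside - inside) as orientation reference
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0};
          for (int v = 0; v < 4; ++v) {
            double p[3] = {wx(g[v]), wy(g[v]), wz(g[v])};
            double* acc = in[v] ? cin : cout;
            acc[0] += p[0]; acc[1] += p[1]; acc[2] += p[2];
          }
          double rx = cout[0] / (4 - nin) - cin[0] / nin;
          double ry = cout[1] / (4 - nin) - cin[1] / nin;
          double rz = cout[2] / (4 - nin) - cin[2] / nin;

          if (nin == 1 || nin == 3) {
            int apex = -1;
            for (int v = 0; v < 4; ++v)
              if (in[v] == (nin == 1)) apex = v;
            int others[3], m = 0;
            for (int v = 0; v < 4; ++v) if (v != apex) others[m++] = v;
            int p0 = edge_pt(g[apex], g[others[0]]);
            int p1 = edge_pt(g[apex], g[others[1]]);
            int p2 = edge_pt(g[apex], g[others[2]]);
            add_tri(p0, p1, p2, rx, ry, rz);
          } else { // nin == 2: quad split into two triangles
            int A = -1, B = -1, C = -1, D = -1;
            for (int v = 0; v < 4; ++v) {
              if (in[v]) { if (A < 0) A = v; else B = v; }
              else       { if (C < 0) C = v; else D = v; }
            }
            int pAC = edge_pt(g[A], g[C]);
            int pAD = edge_pt(g[A], g[D]);
            int pBD = edge_pt(g[B], g[D]);
            int pBC = edge_pt(g[B], g[C]);
            add_tri(pAC, pAD, pBD, rx, ry, rz);
            add_tri(pAC, pBD, pBC, rx, ry, rz);
          }
        }
      }

  const int nv = (int)st.vx.size(), nf = (int)st.f0.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = st.vx[v]; V(v, 1) = st.vy[v]; V(v, 2) = st.vz[v];
  }
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = st.f0[f] + 1; F(f, 1) = st.f1[f] + 1; F(f, 2) = st.f2[f] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
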