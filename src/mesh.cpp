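// Iso-surface extraction (marching tetrahedra on the Kuhn 6-tetrahedra
// decomposition of each grid cell), Taubin/Laplacian smoothing, and signed
// mesh volume. Grid nodes are voxel centers; the volume is virtually padded
// with one below-iso layer so surfaces close at the grid border.

#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

struct V3 { double x, y, z; };
static inline V3 sub(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 cross3(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot3(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

// [[Rcpp::export(name = ".marching_tets")]]
List marching_tets(NumericVector vol, IntegerVector dims, double level,
                   NumericVector spacing, NumericVector origin) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double outside = level - 1.0;
  const double* vp = vol.begin();
  auto val = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= n1 || j < 0 || j >= n2 || k < 0 || k >= n3) return outside;
    return vp[(R_xlen_t)i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)];
  };
  const long long M1 = n1 + 2, M2 = n2 + 2;
  auto nodeid = [&](int i, int j, int k) -> long long {
    return (i + 1) + M1 * ((j + 1) + M2 * (long long)(k + 1));
  };

  std::unordered_map<unsigned long long, int> edge_map;
  std::vector<double> vx, vy, vz;   // vertex coords (index space)
  std::vector<int> tris;            // 0-based vertex indices

  // corner offsets, corner m = dx + 2*dy + 4*dz
  const int OFF[8][3] = {{0,0,0},{1,0,0},{0,1,0},{1,1,0},
                         {0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  const int PERM[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  const int BIT[3] = {1, 2, 4};

  double cv[8];
  int ci[8], cj[8], ck[8];

  auto cut_vertex = [&](int m_in, int m_out) -> int {
    int a = m_in, b = m_out;
    long long ia = nodeid(ci[a], cj[a], ck[a]), ib = nodeid(ci[b], cj[b], ck[b]);
    unsigned long long key;
    bool swapped = ia > ib;
    long long lo = swapped ? ib : ia, hi = swapped ? ia : ib;
    key = (unsigned long long)lo * 0x100000000ULL ^ (unsigned long long)hi;
    // combine without collision: lo,hi < (n+2)^3 <= 2^31 for any sane grid
    key = ((unsigned long long)lo << 32) | (unsigned long long)hi;
    auto it = edge_map.find(key);
    if (it != edge_map.end()) return it->second;
    double va = cv[a], vb = cv[b];
    double t = (level - va) / (vb - va);
    if (t < 0) t = 0; if (t > 1) t = 1;
    double px = ci[a] + t * (ci[b] - ci[a]);
    double py = cj[a] + t * (cj[b] - cj[a]);
    double pz = ck[a] + t * (ck[b] - ck[a]);
    int id = (int)vx.size();
    vx.push_back(px); vy.push_back(py); vz.push_back(pz);
    edge_map.emplace(key, id);
    return id;
  };

  auto emit = [&](int p1, int p2, int p3, V3 ref) {
    V3 a = {vx[p1], vy[p1], vz[p1]};
    V3 b = {vx[p2], vy[p2], vz[p2]};
    V3 c = {vx[p3], vy[p3], vz[p3]};
    V3 n = cross3(sub(b, a), sub(c, a));
    double nn = dot3(n, n);
    if (nn < 1e-24) return;  // zero-area, drop
    V3 cen = {(a.x + b.x + c.x) / 3, (a.y + b.y + c.y) / 3, (a.z + b.z + c.z) / 3};
    if (dot3(n, sub(ref, cen)) > 0) std::swap(p2, p3);  // normal away from inside
    tris.push_back(p1); tris.push_back(p2); tris.push_back(p3);
  };

  for (int k = -1; k < n3; ++k)
    for (int j = -1; j < n2; ++j)
      for (int i = -1; i < n1; ++i) {
        bool any_in = false, any_out = false;
        for (int m = 0; m < 8; ++m) {
          ci[m] = i + OFF[m][0]; cj[m] = j + OFF[m][1]; ck[m] = k + OFF[m][2];
          cv[m] = val(ci[m], cj[m], ck[m]);
          if (cv[m] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int p = 0; p < 6; ++p) {
          int tv[4];
          tv[0] = 0;
          tv[1] = BIT[PERM[p][0]];
          tv[2] = tv[1] | BIT[PERM[p][1]];
          tv[3] = 7;
          int ins[4], outs[4], ni = 0, no = 0;
          for (int q = 0; q < 4; ++q) {
            if (cv[tv[q]] > level) ins[ni++] = tv[q]; else outs[no++] = tv[q];
          }
          if (ni == 0 || ni == 4) continue;
          // reference interior point: centroid of inside corners
          V3 ref = {0, 0, 0};
          for (int q = 0; q < ni; ++q) {
            ref.x += ci[ins[q]]; ref.y += cj[ins[q]]; ref.z += ck[ins[q]];
          }
          ref.x /= ni; ref.y /= ni; ref.z /= ni;
          if (ni == 1) {
            int a = cut_vertex(ins[0], outs[0]);
            int b = cut_vertex(ins[0], outs[1]);
            int c = cut_vertex(ins[0], outs[2]);
            emit(a, b, c, ref);
          } else if (ni == 3) {
            int a = cut_vertex(ins[0], outs[0]);
            int b = cut_vertex(ins[1], outs[0]);
            int c = cut_vertex(ins[2], outs[0]);
            emit(a, b, c, ref);
          } else {  // 2-2: quad
            int a = cut_vertex(ins[0], outs[0]);
            int b = cut_vertex(ins[0], outs[1]);
            int c = cut_vertex(ins[1], outs[1]);
            int d = cut_vertex(ins[1], outs[0]);
            emit(a, b, c, ref);
            emit(a, c, d, ref);
          }
        }
      }

  int nv = (int)vx.size(), nt = (int)tris.size() / 3;
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = origin[0] + vx[v] * spacing[0];
    V(v, 1) = origin[1] + vy[v] * spacing[1];
    V(v, 2) = origin[2] + vz[v] * spacing[2];
  }
  IntegerMatrix F(nt, 3);
  for (int t = 0; t < nt; ++t) {
    F(t, 0) = tris[3 * t] + 1;
    F(t, 1) = tris[3 * t + 1] + 1;
    F(t, 2) = tris[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = F);
}

// [[Rcpp::export(name = ".mesh_volume_cpp")]]
double mesh_volume_cpp(NumericMatrix V, IntegerMatrix F) {
  double vol = 0.0;
  for (int t = 0; t < F.nrow(); ++t) {
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    V3 p1 = {V(a, 0), V(a, 1), V(a, 2)};
    V3 p2 = {V(b, 0), V(b, 1), V(b, 2)};
    V3 p3 = {V(c, 0), V(c, 1), V(c, 2)};
    vol += dot3(p1, cross3(p2, p3)) / 6.0;
  }
  return vol;
}

// Two-factor smoothing: per iteration move vertices by factor1 * umbrella
// Laplacian, then (if factor2 != 0) by factor2 * umbrella Laplacian.
// Taubin: factor1 = lambda > 0, factor2 = mu < 0. Laplacian-only: factor2 = 0.
// [[Rcpp::export(name = ".smooth_mesh_cpp")]]
NumericMatrix smooth_mesh_cpp(NumericMatrix V, IntegerMatrix F, double factor1,
                              double factor2, int iterations) {
  int nv = V.nrow(), nt = F.nrow();
  // build unique undirected adjacency (CSR)
  std::vector<std::vector<int>> adj(nv);
  auto add_edge = [&](int a, int b) {
    adj[a].push_back(b);
    adj[b].push_back(a);
  };
  for (int t = 0; t < nt; ++t) {
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    add_edge(a, b); add_edge(b, c); add_edge(c, a);
  }
  for (int v = 0; v < nv; ++v) {
    std::sort(adj[v].begin(), adj[v].end());
    adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
  }
  std::vector<double> X(nv), Y(nv), Z(nv), nX(nv), nY(nv), nZ(nv);
  for (int v = 0; v < nv; ++v) { X[v] = V(v, 0); Y[v] = V(v, 1); Z[v] = V(v, 2); }
  auto pass = [&](double f) {
    if (f == 0.0) return;
    for (int v = 0; v < nv; ++v) {
      size_t deg = adj[v].size();
      if (deg == 0) { nX[v] = X[v]; nY[v] = Y[v]; nZ[v] = Z[v]; continue; }
      double mx = 0, my = 0, mz = 0;
      for (int u : adj[v]) { mx += X[u]; my += Y[u]; mz += Z[u]; }
      mx /= deg; my /= deg; mz /= deg;
      nX[v] = X[v] + f * (mx - X[v]);
      nY[v] = Y[v] + f * (my - Y[v]);
      nZ[v] = Z[v] + f * (mz - Z[v]);
    }
    X.swap(nX); Y.swap(nY); Z.swap(nZ);
  };
  for (int it = 0; it < iterations; ++it) {
    pass(factor1);
    pass(factor2);
  }
  NumericMatrix out(nv, 3);
  for (int v = 0; v < nv; ++v) { out(v, 0) = X[v]; out(v, 1) = Y[v]; out(v, 2) = Z[v]; }
  return out;
}
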