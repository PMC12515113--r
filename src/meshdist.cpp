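// Point-to-surface distances (uniform-grid accelerated) and mesh
// voxelization by z-column ray parity. Used by the ASD metric and by the
// volumetric (mesh-mode) Dice computation.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct P3 { double x, y, z; };
static inline P3 operator-(P3 a, P3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline double dt(P3 a, P3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

// Ericson, Real-Time Collision Detection: squared distance point-triangle.
double pt_tri_d2(P3 p, P3 a, P3 b, P3 c) {
  P3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dt(ab, ap), d2 = dt(ac, ap);
  if (d1 <= 0 && d2 <= 0) return dt(ap, ap);
  P3 bp = p - b;
  double d3 = dt(ab, bp), d4 = dt(ac, bp);
  if (d3 >= 0 && d4 <= d3) return dt(bp, bp);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    P3 q = {ap.x - v * ab.x, ap.y - v * ab.y, ap.z - v * ab.z};
    return dt(q, q);
  }
  P3 cp = p - c;
  double d5 = dt(ab, cp), d6 = dt(ac, cp);
  if (d6 >= 0 && d5 <= d6) return dt(cp, cp);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    P3 q = {ap.x - w * ac.x, ap.y - w * ac.y, ap.z - w * ac.z};
    return dt(q, q);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    P3 q = {p.x - (b.x + w * (c.x - b.x)), p.y - (b.y + w * (c.y - b.y)),
            p.z - (b.z + w * (c.z - b.z))};
    return dt(q, q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  P3 q = {p.x - (a.x + v * ab.x + w * ac.x), p.y - (a.y + v * ab.y + w * ac.y),
          p.z - (a.z + v * ab.z + w * ac.z)};
  return dt(q, q);
}

}  // namespace

// [[Rcpp::export(name = ".point_mesh_dist")]]
NumericVector point_mesh_dist(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nt = F.nrow();
  NumericVector out(np);
  // mesh bbox and grid
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int v = 0; v < V.nrow(); ++v)
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], V(v, a));
      hi[a] = std::max(hi[a], V(v, a));
    }
  double diag = 0;
  for (int a = 0; a < 3; ++a) diag = std::max(diag, hi[a] - lo[a]);
  double h = std::max(diag / 48.0, 1e-9);
  int ng[3];
  for (int a = 0; a < 3; ++a)
    ng[a] = std::max(1, (int)std::ceil((hi[a] - lo[a]) / h) + 1);
  auto cell_of = [&](double w, int a) {
    int c = (int)std::floor((w - lo[a]) / h);
    return std::min(std::max(c, 0), ng[a] - 1);
  };
  std::vector<std::vector<int>> bins((size_t)ng[0] * ng[1] * ng[2]);
  auto bin_idx = [&](int cx, int cy, int cz) {
    return (size_t)cx + (size_t)ng[0] * (cy + (size_t)ng[1] * cz);
  };
  for (int t = 0; t < nt; ++t) {
    double tlo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double thi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int q = 0; q < 3; ++q) {
      int v = F(t, q) - 1;
      for (int a = 0; a < 3; ++a) {
        tlo[a] = std::min(tlo[a], V(v, a));
        thi[a] = std::max(thi[a], V(v, a));
      }
    }
    int c0[3], c1[3];
    for (int a = 0; a < 3; ++a) {
      c0[a] = cell_of(tlo[a], a);
      c1[a] = cell_of(thi[a], a);
    }
    for (int cz = c0[2]; cz <= c1[2]; ++cz)
      for (int cy = c0[1]; cy <= c1[1]; ++cy)
        for (int cx = c0[0]; cx <= c1[0]; ++cx)
          bins[bin_idx(cx, cy, cz)].push_back(t);
  }
  int maxring = std::max(std::max(ng[0], ng[1]), ng[2]);
  for (int ip = 0; ip < np; ++ip) {
    P3 p = {P(ip, 0), P(ip, 1), P(ip, 2)};
    int pc[3] = {cell_of(p.x, 0), cell_of(p.y, 1), cell_of(p.z, 2)};
    double best = R_PosInf;
    for (int r = 0; r <= maxring; ++r) {
      bool scanned_any = false;
      int x0 = std::max(0, pc[0] - r), x1 = std::min(ng[0] - 1, pc[0] + r);
      int y0 = std::max(0, pc[1] - r), y1 = std::min(ng[1] - 1, pc[1] + r);
      int z0 = std::max(0, pc[2] - r), z1 = std::min(ng[2] - 1, pc[2] + r);
      for (int cz = z0; cz <= z1; ++cz)
        for (int cy = y0; cy <= y1; ++cy)
          for (int cx = x0; cx <= x1; ++cx) {
            // only the new shell at radius r
            if (r > 0 && std::abs(cx - pc[0]) != r && std::abs(cy - pc[1]) != r &&
                std::abs(cz - pc[2]) != r)
              continue;
            const std::vector<int>& B = bins[bin_idx(cx, cy, cz)];
            for (int t : B) {
              int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
              P3 pa = {V(a, 0), V(a, 1), V(a, 2)};
              P3 pb = {V(b, 0), V(b, 1), V(b, 2)};
              P3 pcv = {V(c, 0), V(c, 1), V(c, 2)};
              double d2 = pt_tri_d2(p, pa, pb, pcv);
              if (d2 < best) best = d2;
            }
            scanned_any = true;
          }
      (void)scanned_any;
      if (std::isfinite(best)) {
        // distance from p to the boundary of the scanned block
        double dout = R_PosInf;
        double bx0 = lo[0] + (pc[0] - r) * h, bx1 = lo[0] + (pc[0] + r + 1) * h;
        double by0 = lo[1] + (pc[1] - r) * h, by1 = lo[1] + (pc[1] + r + 1) * h;
        double bz0 = lo[2] + (pc[2] - r) * h, bz1 = lo[2] + (pc[2] + r + 1) * h;
        dout = std::min(dout, p.x - bx0); dout = std::min(dout, bx1 - p.x);
        dout = std::min(dout, p.y - by0); dout = std::min(dout, by1 - p.y);
        dout = std::min(dout, p.z - bz0); dout = std::min(dout, bz1 - p.z);
        bool covered = (x0 == 0 && y0 == 0 && z0 == 0 && x1 == ng[0] - 1 &&
                        y1 == ng[1] - 1 && z1 == ng[2] - 1);
        if (covered || std::sqrt(best) <= dout) break;
      }
    }
    out[ip] = std::sqrt(best);
  }
  return out;
}

// Voxelize a closed mesh on a grid (voxel centers origin + idx*spacing) by
// parity of z-ray crossings per (x, y) column. A tiny irrational offset on
// the ray position avoids hits exactly on triangle edges.
// [[Rcpp::export(name = ".voxelize_mesh")]]
IntegerVector voxelize_mesh(NumericMatrix V, IntegerMatrix F,
                            NumericVector origin, NumericVector spacing,
                            IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double eps = 1e-7 * (spacing[0] + spacing[1]);
  std::vector<std::vector<double>> crossings((size_t)nx * ny);
  for (int t = 0; t < F.nrow(); ++t) {
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    double ax = V(a, 0), ay = V(a, 1), az = V(a, 2);
    double bx = V(b, 0), by = V(b, 1), bz = V(b, 2);
    double cx = V(c, 0), cy = V(c, 1), cz = V(c, 2);
    double xlo = std::min(ax, std::min(bx, cx)), xhi = std::max(ax, std::max(bx, cx));
    double ylo = std::min(ay, std::min(by, cy)), yhi = std::max(ay, std::max(by, cy));
    int i0 = std::max(0, (int)std::ceil((xlo - origin[0]) / spacing[0] - 0.5));
    int i1 = std::min(nx - 1, (int)std::floor((xhi - origin[0]) / spacing[0] + 0.5));
    int j0 = std::max(0, (int)std::ceil((ylo - origin[1]) / spacing[1] - 0.5));
    int j1 = std::min(ny - 1, (int)std::floor((yhi - origin[1]) / spacing[1] + 0.5));
    double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (std::abs(det) < 1e-14) continue;  // vertical / degenerate in xy
    for (int j = j0; j <= j1; ++j) {
      double py = origin[1] + j * spacing[1] + eps * 0.7071;
      for (int i = i0; i <= i1; ++i) {
        double px = origin[0] + i * spacing[0] + eps;
        double l1 = ((bx - px) * (cy - py) - (by - py) * (cx - px)) / det;
        double l2 = ((cx - px) * (ay - py) - (cy - py) * (ax - px)) / det;
        double l3 = 1.0 - l1 - l2;
        if (l1 <= 0 || l2 <= 0 || l3 <= 0) continue;
        double z = l1 * az + l2 * bz + l3 * cz;
        crossings[(size_t)i + (size_t)nx * j].push_back(z);
      }
    }
  }
  IntegerVector out((R_xlen_t)nx * ny * nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      std::vector<double>& cz = crossings[(size_t)i + (size_t)nx * j];
      if (cz.empty()) continue;
      std::sort(cz.begin(), cz.end());
      size_t npairs = cz.size() / 2;
      for (size_t m = 0; m < npairs; ++m) {
        double zlo = cz[2 * m], zhi = cz[2 * m + 1];
        int k0 = std::max(0, (int)std::ceil((zlo - origin[2]) / spacing[2]));
        int k1 = std::min(nz - 1, (int)std::floor((zhi - origin[2]) / spacing[2]));
        for (int k = k0; k <= k1; ++k)
          out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = 1;
      }
    }
  out.attr("dim") = dims;
  return out;
}

// 26-connected component labelling of a binary mask.
// [[Rcpp::export(name = ".label_components26")]]
IntegerVector label_components26(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab((R_xlen_t)nx * ny * nz);
  const int* mp = mask.begin();
  int* lp = lab.begin();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < lab.size(); ++s) {
    if (!mp[s] || lp[s]) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    lp[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx), j = (int)((cur / nx) % ny), k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            R_xlen_t q = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mp[q] && !lp[q]) {
              lp[q] = next;
              stack.push_back(q);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
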