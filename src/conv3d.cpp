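// Minimal 3D convolution / pooling primitives for the CPU U-Net.
// Tensor layout: R arrays of dim (D, H, W, C) — spatial-major, channel last,
// so each channel is a contiguous block of N = D*H*W doubles.
// 3x3x3 convolution (zero padding 1) is computed directly as 27 shifted
// axpy/dot sweeps per channel pair; no im2col intermediates are built.
// Weights are (C*27) x K matrices; row index = c*27 + offset, with offset
// enumerating (di, dj, dk) in di-fastest order over {-1,0,1}^3.

#include <Rcpp.h>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

static inline R_xlen_t spat(int i, int j, int k, int D, int H) {
  return (R_xlen_t)i + (R_xlen_t)D * ((R_xlen_t)j + (R_xlen_t)H * k);
}

// offset index o = (di+1) + 3*(dj+1) + 9*(dk+1), di fastest
// Convolution arithmetic runs in single precision internally (the API stays
// double): network weights/activations never need 1e-7 relative accuracy and
// the narrower lanes double SIMD throughput on these row sweeps.
static inline void row_axpy(float* y, const float* x, float w, int i0,
                            int i1, int di) {
  const float* xs = x + di;
  for (int i = i0; i < i1; ++i) y[i] += w * xs[i];
}

// fused: y[i] += w0*x[i-1] + w1*x[i] + w2*x[i+1] (interior), edges separate
static inline void row_axpy3(float* y, const float* x, float w0, float w1,
                             float w2, int D) {
  y[0] += w1 * x[0] + w2 * x[1];
  for (int i = 1; i < D - 1; ++i)
    y[i] += w0 * x[i - 1] + w1 * x[i] + w2 * x[i + 1];
  y[D - 1] += w0 * x[D - 2] + w1 * x[D - 1];
}

// fused correlation: a0 += g[i]*x[i-1], a1 += g[i]*x[i], a2 += g[i]*x[i+1]
static inline void row_dot3(const float* g, const float* x, float& a0,
                            float& a1, float& a2, int D) {
  float s0 = 0, s1 = 0, s2 = 0;
  for (int i = 1; i < D - 1; ++i) {
    float gi = g[i];
    s0 += gi * x[i - 1];
    s1 += gi * x[i];
    s2 += gi * x[i + 1];
  }
  s1 += g[0] * x[0] + g[D - 1] * x[D - 1];
  s2 += g[0] * x[1];
  s0 += g[D - 1] * x[D - 2];
  a0 += s0; a1 += s1; a2 += s2;
}

// [[Rcpp::export(name = ".conv3_forward")]]
NumericVector conv3_forward(NumericVector x, IntegerVector dims,
                            NumericMatrix w, NumericVector b, int ksize) {
  int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const R_xlen_t N = (R_xlen_t)D * H * W;
  int K = w.ncol();
  NumericVector y(N * K);
  std::vector<float> xf(x.begin(), x.end());
  std::vector<float> wf(w.begin(), w.end());
  std::vector<float> yf(N * K);
  const float* xp = xf.data();
  for (int k = 0; k < K; ++k) {
    float* yk = yf.data() + (R_xlen_t)k * N;
    std::fill(yk, yk + N, (float)b[k]);
    if (ksize == 1) {
      for (int c = 0; c < C; ++c) {
        const float* xc = xp + (R_xlen_t)c * N;
        float wv = wf[(size_t)k * C + c];
        if (wv != 0)
          for (R_xlen_t s = 0; s < N; ++s) yk[s] += wv * xc[s];
      }
      continue;
    }
    for (int kz = 0; kz < W; ++kz)
      for (int j = 0; j < H; ++j) {
        float* yrow = yk + spat(0, j, kz, D, H);
        for (int c = 0; c < C; ++c) {
          const float* xc = xp + (R_xlen_t)c * N;
          const float* wc = wf.data() + (size_t)k * (27 * C) + (size_t)c * 27;
          for (int dk = -1; dk <= 1; ++dk) {
            int ks = kz + dk;
            if (ks < 0 || ks >= W) continue;
            for (int dj = -1; dj <= 1; ++dj) {
              int js = j + dj;
              if (js < 0 || js >= H) continue;
              const float* xrow = xc + spat(0, js, ks, D, H);
              int ob = (dj + 1) * 3 + (dk + 1) * 9 + 1;
              row_axpy3(yrow, xrow, wc[ob - 1], wc[ob], wc[ob + 1], D);
            }
          }
        }
      }
  }
  std::copy(yf.begin(), yf.end(), y.begin());
  y.attr("dim") = IntegerVector::create(D, H, W, K);
  return y;
}

// [[Rcpp::export(name = ".conv3_backward")]]
List conv3_backward(NumericVector x, IntegerVector dims, NumericMatrix w,
                    NumericVector gout, int ksize) {
  int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const R_xlen_t N = (R_xlen_t)D * H * W;
  int K = w.ncol();
  NumericVector gx(N * C);
  NumericMatrix gw(w.nrow(), w.ncol());
  NumericVector gb(K);
  std::vector<float> xf(x.begin(), x.end());
  std::vector<float> wf(w.begin(), w.end());
  std::vector<float> gf(gout.begin(), gout.end());
  std::vector<float> gxf((size_t)N * C, 0.0f);
  const float* xp = xf.data();
  std::vector<double> acc((size_t)27 * C);
  const int wrow = w.nrow();
  for (int k = 0; k < K; ++k) {
    const float* gk = gf.data() + (R_xlen_t)k * N;
    double s = 0.0;
    for (R_xlen_t t = 0; t < N; ++t) s += gk[t];
    gb[k] = s;
    if (ksize == 1) {
      for (int c = 0; c < C; ++c) {
        const float* xc = xp + (R_xlen_t)c * N;
        float* gxc = gxf.data() + (R_xlen_t)c * N;
        float wv = wf[(size_t)k * C + c];
        double a = 0.0;
        for (R_xlen_t t = 0; t < N; ++t) {
          a += (double)gk[t] * xc[t];
          gxc[t] += wv * gk[t];
        }
        gw(c, k) = a;
      }
      continue;
    }
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int kz = 0; kz < W; ++kz)
      for (int j = 0; j < H; ++j) {
        const float* grow = gk + spat(0, j, kz, D, H);
        for (int c = 0; c < C; ++c) {
          const float* xc = xp + (R_xlen_t)c * N;
          float* gxc = gxf.data() + (R_xlen_t)c * N;
          const float* wc = wf.data() + (size_t)k * wrow + (size_t)c * 27;
          double* ac = &acc[(size_t)c * 27];
          for (int dk = -1; dk <= 1; ++dk) {
            int ks = kz + dk;
            if (ks < 0 || ks >= W) continue;
            for (int dj = -1; dj <= 1; ++dj) {
              int js = j + dj;
              if (js < 0 || js >= H) continue;
              const float* xrow = xc + spat(0, js, ks, D, H);
              float* gxrow = gxc + spat(0, js, ks, D, H);
              int ob = (dj + 1) * 3 + (dk + 1) * 9 + 1;
              // weight grads: correlate gout row with shifted x rows
              float a0 = 0, a1 = 0, a2 = 0;
              row_dot3(grow, xrow, a0, a1, a2, D);
              ac[ob - 1] += a0;
              ac[ob] += a1;
              ac[ob + 1] += a2;
              // input grads: transpose conv (scatter gout onto x rows with
              // negated offsets), fused over di
              row_axpy3(gxrow, grow, wc[ob + 1], wc[ob], wc[ob - 1], D);
            }
          }
        }
      }
    for (int c = 0; c < C; ++c)
      for (int o = 0; o < 27; ++o) gw(c * 27 + o, k) = acc[(size_t)c * 27 + o];
  }
  std::copy(gxf.begin(), gxf.end(), gx.begin());
  gx.attr("dim") = IntegerVector::create(D, H, W, C);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling; returns pooled tensor and flat argmax indices (0-based).
// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x, IntegerVector dims) {
  int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  int d = D / 2, h = H / 2, wo = W / 2;
  const R_xlen_t N = (R_xlen_t)D * H * W;
  const R_xlen_t n = (R_xlen_t)d * h * wo;
  NumericVector y(n * C);
  IntegerVector idx(n * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)c * N;
    double* yc = y.begin() + (R_xlen_t)c * n;
    int* ic = idx.begin() + (R_xlen_t)c * n;
    for (int k = 0; k < wo; ++k)
      for (int j = 0; j < h; ++j)
        for (int i = 0; i < d; ++i) {
          double best = -1e300;
          R_xlen_t bi = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                R_xlen_t s = spat(2 * i + di, 2 * j + dj, 2 * k + dk, D, H);
                if (xc[s] > best) { best = xc[s]; bi = s; }
              }
          R_xlen_t o = spat(i, j, k, d, h);
          yc[o] = best;
          ic[o] = (int)bi;
        }
  }
  y.attr("dim") = IntegerVector::create(d, h, wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(NumericVector gy, IntegerVector idx,
                                IntegerVector dims) {
  int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const R_xlen_t N = (R_xlen_t)D * H * W;
  const R_xlen_t n = (R_xlen_t)gy.size() / C;
  NumericVector gx(N * C);
  for (int c = 0; c < C; ++c) {
    const double* g = gy.begin() + (R_xlen_t)c * n;
    const int* ic = idx.begin() + (R_xlen_t)c * n;
    double* gc = gx.begin() + (R_xlen_t)c * N;
    for (R_xlen_t o = 0; o < n; ++o) gc[ic[o]] += g[o];
  }
  gx.attr("dim") = dims;
  return gx;
}

// Nearest-neighbour 2x upsampling and its adjoint.
// [[Rcpp::export(name = ".upsample2_forward")]]
NumericVector upsample2_forward(NumericVector x, IntegerVector dims) {
  int d = dims[0], h = dims[1], w = dims[2], C = dims[3];
  int D = 2 * d, H = 2 * h, W = 2 * w;
  const R_xlen_t n = (R_xlen_t)d * h * w, N = (R_xlen_t)D * H * W;
  NumericVector y(N * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (R_xlen_t)c * n;
    double* yc = y.begin() + (R_xlen_t)c * N;
    for (int k = 0; k < W; ++k)
      for (int j = 0; j < H; ++j) {
        const double* row = xc + spat(0, j / 2, k / 2, d, h);
        double* out = yc + spat(0, j, k, D, H);
        for (int i = 0; i < D; ++i) out[i] = row[i / 2];
      }
  }
  y.attr("dim") = IntegerVector::create(D, H, W, C);
  return y;
}

// [[Rcpp::export(name = ".upsample2_backward")]]
NumericVector upsample2_backward(NumericVector gy, IntegerVector dims_small) {
  int d = dims_small[0], h = dims_small[1], w = dims_small[2], C = dims_small[3];
  int D = 2 * d, H = 2 * h, W = 2 * w;
  const R_xlen_t n = (R_xlen_t)d * h * w, N = (R_xlen_t)D * H * W;
  NumericVector gx(n * C);
  for (int c = 0; c < C; ++c) {
    const double* g = gy.begin() + (R_xlen_t)c * N;
    double* gc = gx.begin() + (R_xlen_t)c * n;
    for (int k = 0; k < W; ++k)
      for (int j = 0; j < H; ++j) {
        double* out = gc + spat(0, j / 2, k / 2, d, h);
        const double* row = g + spat(0, j, k, D, H);
        for (int i = 0; i < D; ++i) out[i / 2] += row[i];
      }
  }
  gx.attr("dim") = IntegerVector::create(d, h, w, C);
  return gx;
}
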