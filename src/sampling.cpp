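// Volume resampling / warping in index space.
// The source location of output voxel o (0-based index triple) is
//   s = A[,1:3] %*% o + A[,4] + disp[o, ]  (disp optional, in source voxels)
// Sampling is trilinear (mode 1) or nearest-neighbour (mode 0) with a
// constant fill value outside the source grid.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".warp_volume")]]
NumericVector warp_volume(NumericVector src, IntegerVector sdim,
                          IntegerVector odim, NumericMatrix A,
                          Nullable<NumericVector> disp, int mode, double fill) {
  const int sd = sdim[0], sh = sdim[1], sw = sdim[2];
  const int od = odim[0], oh = odim[1], ow = odim[2];
  const double* xp = src.begin();
  NumericVector out((R_xlen_t)od * oh * ow);
  double* op = out.begin();
  const double* dp = nullptr;
  R_xlen_t n = (R_xlen_t)od * oh * ow;
  if (disp.isNotNull()) {
    NumericVector d(disp);
    if (d.size() != 3 * n) stop("displacement field size mismatch");
    dp = d.begin();
  }
  R_xlen_t o = 0;
  for (int k = 0; k < ow; ++k)
    for (int j = 0; j < oh; ++j)
      for (int i = 0; i < od; ++i, ++o) {
        double x = A(0, 0) * i + A(0, 1) * j + A(0, 2) * k + A(0, 3);
        double y = A(1, 0) * i + A(1, 1) * j + A(1, 2) * k + A(1, 3);
        double z = A(2, 0) * i + A(2, 1) * j + A(2, 2) * k + A(2, 3);
        if (dp) { x += dp[o]; y += dp[o + n]; z += dp[o + 2 * n]; }
        double v;
        if (mode == 0) {
          int ii = (int)std::floor(x + 0.5), jj = (int)std::floor(y + 0.5),
              kk = (int)std::floor(z + 0.5);
          if (ii < 0 || ii >= sd || jj < 0 || jj >= sh || kk < 0 || kk >= sw)
            v = fill;
          else
            v = xp[(R_xlen_t)ii + (R_xlen_t)sd * (jj + (R_xlen_t)sh * kk)];
        } else {
          int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
              k0 = (int)std::floor(z);
          double fx = x - i0, fy = y - j0, fz = z - k0;
          v = 0.0;
          double wsum = 0.0;
          bool any_out = false;
          for (int dk = 0; dk <= 1; ++dk)
            for (int dj = 0; dj <= 1; ++dj)
              for (int di = 0; di <= 1; ++di) {
                double wgt = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                             (dk ? fz : 1 - fz);
                if (wgt <= 0) continue;
                int ii = i0 + di, jj = j0 + dj, kk = k0 + dk;
                if (ii < 0 || ii >= sd || jj < 0 || jj >= sh || kk < 0 ||
                    kk >= sw) {
                  v += wgt * fill;
                  any_out = true;
                } else {
                  v += wgt *
                       xp[(R_xlen_t)ii + (R_xlen_t)sd * (jj + (R_xlen_t)sh * kk)];
                }
                wsum += wgt;
              }
          (void)any_out;
          (void)wsum;
        }
        op[o] = v;
      }
  out.attr("dim") = IntegerVector::create(od, oh, ow);
  return out;
}
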