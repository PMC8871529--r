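// Image-space helpers: brute-force bilateral filter, 2-D correlation with
// reflected borders, partial-volume sphere rasterisation, trilinear resize.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // symmetric half-sample reflection: -1 -> 0, n -> n-1
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Joint/guided bilateral: range weights from `guide`, averaged values from
// `img`. The classic bilateral is guide == img.
// [[Rcpp::export]]
arma::mat cpp_bilateral_guided(const arma::mat &img, const arma::mat &guide,
                               double sigma_d, double sigma_r) {
  const int nr = img.n_rows, nc = img.n_cols;
  const int rad = (int)std::ceil(3.0 * sigma_d);
  arma::mat gs(2 * rad + 1, 2 * rad + 1);
  for (int dr = -rad; dr <= rad; ++dr)
    for (int dc = -rad; dc <= rad; ++dc)
      gs(dr + rad, dc + rad) =
          std::exp(-0.5 * (dr * dr + dc * dc) / (sigma_d * sigma_d));
  arma::mat out(nr, nc);
  const double inv2sr2 = 0.5 / (sigma_r * sigma_r);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double g0 = guide(r, c);
      double num = 0.0, den = 0.0;
      for (int dc = -rad; dc <= rad; ++dc) {
        const int cc = reflect_idx(c + dc, nc);
        for (int dr = -rad; dr <= rad; ++dr) {
          const int rr = reflect_idx(r + dr, nr);
          const double d = guide(rr, cc) - g0;
          const double w = gs(dr + rad, dc + rad) * std::exp(-d * d * inv2sr2);
          num += w * img(rr, cc);
          den += w;
        }
      }
      out(r, c) = num / den;
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_bilateral(const arma::mat &img, double sigma_d, double sigma_r) {
  return cpp_bilateral_guided(img, img, sigma_d, sigma_r);
}

// 2-D correlation with a centred odd-sized kernel, reflected borders.
// [[Rcpp::export]]
arma::mat cpp_filter2(const arma::mat &img, const arma::mat &ker) {
  const int nr = img.n_rows, nc = img.n_cols;
  const int kr = ker.n_rows / 2, kc = ker.n_cols / 2;
  arma::mat out(nr, nc, arma::fill::zeros);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int dc = -kc; dc <= kc; ++dc) {
        const int cc = reflect_idx(c + dc, nc);
        for (int dr = -kr; dr <= kr; ++dr)
          acc += ker(dr + kr, dc + kc) * img(reflect_idx(r + dr, nr), cc);
      }
      out(r, c) = acc;
    }
  return out;
}

// Add a partial-volume weighted (spheroidal) feature to a volume and return
// the modified copy. Voxels wholly inside get weight 1, boundary voxels the
// sub-sampled inside fraction (nsub^3 samples). zaspect scales the z semi-axis.
// [[Rcpp::export]]
NumericVector cpp_add_spheroid(NumericVector mu, IntegerVector dims,
                               double voxel, NumericVector center,
                               double radius, double zaspect, double contrast,
                               int nsub) {
  NumericVector out = clone(mu);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double rz = radius * zaspect;
  const double half_diag = 0.5 * voxel * std::sqrt(3.0);
  const int ix0 = std::max(0, (int)std::floor((center[0] - radius) / voxel) - 1);
  const int ix1 = std::min(nx - 1, (int)std::ceil((center[0] + radius) / voxel) + 1);
  const int iy0 = std::max(0, (int)std::floor((center[1] - radius) / voxel) - 1);
  const int iy1 = std::min(ny - 1, (int)std::ceil((center[1] + radius) / voxel) + 1);
  const int iz0 = std::max(0, (int)std::floor((center[2] - rz) / voxel) - 1);
  const int iz1 = std::min(nz - 1, (int)std::ceil((center[2] + rz) / voxel) + 1);
  double *p = REAL(out);
  for (int iz = iz0; iz <= iz1; ++iz)
    for (int iy = iy0; iy <= iy1; ++iy)
      for (int ix = ix0; ix <= ix1; ++ix) {
        const double x = (ix + 0.5) * voxel - center[0];
        const double y = (iy + 0.5) * voxel - center[1];
        const double z = ((iz + 0.5) * voxel - center[2]) / zaspect;
        const double d = std::sqrt(x * x + y * y + z * z);
        double w;
        if (d <= radius - half_diag) {
          w = 1.0;
        } else if (d >= radius + half_diag) {
          w = 0.0;
        } else {
          int inside = 0;
          for (int sz = 0; sz < nsub; ++sz)
            for (int sy = 0; sy < nsub; ++sy)
              for (int sx = 0; sx < nsub; ++sx) {
                const double xx = x + ((sx + 0.5) / nsub - 0.5) * voxel;
                const double yy = y + ((sy + 0.5) / nsub - 0.5) * voxel;
                const double zz = z + ((sz + 0.5) / nsub - 0.5) * voxel / zaspect;
                if (xx * xx + yy * yy + zz * zz <= radius * radius) ++inside;
              }
          w = (double)inside / (nsub * nsub * nsub);
        }
        if (w > 0)
          p[(size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz)] +=
              contrast * w;
      }
  return out;
}

// Trilinear resize of a 3-D array onto a new grid spanning the same physical
// extent (cell-centred sampling on both grids).
// [[Rcpp::export]]
NumericVector cpp_resize3(NumericVector x, IntegerVector dims,
                          IntegerVector newdims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = newdims[0], my = newdims[1], mz = newdims[2];
  NumericVector out((size_t)mx * my * mz);
  const double *px = REAL(x);
  double *po = REAL(out);
  const double sx = (double)nx / mx, sy = (double)ny / my, sz = (double)nz / mz;
  for (int k = 0; k < mz; ++k) {
    double fz = (k + 0.5) * sz - 0.5;
    int iz = (int)std::floor(fz);
    double wz = fz - iz;
    int iz0 = std::min(std::max(iz, 0), nz - 1);
    int iz1 = std::min(std::max(iz + 1, 0), nz - 1);
    for (int j = 0; j < my; ++j) {
      double fy = (j + 0.5) * sy - 0.5;
      int iy = (int)std::floor(fy);
      double wy = fy - iy;
      int iy0 = std::min(std::max(iy, 0), ny - 1);
      int iy1 = std::min(std::max(iy + 1, 0), ny - 1);
      for (int i = 0; i < mx; ++i) {
        double fx = (i + 0.5) * sx - 0.5;
        int ix = (int)std::floor(fx);
        double wx = fx - ix;
        int ix0 = std::min(std::max(ix, 0), nx - 1);
        int ix1 = std::min(std::max(ix + 1, 0), nx - 1);
#define MU(a, b, c) px[(size_t)(a) + (size_t)nx * ((size_t)(b) + (size_t)ny * (c))]
        double v =
            (1 - wz) * ((1 - wy) * ((1 - wx) * MU(ix0, iy0, iz0) + wx * MU(ix1, iy0, iz0)) +
                        wy * ((1 - wx) * MU(ix0, iy1, iz0) + wx * MU(ix1, iy1, iz0))) +
            wz * ((1 - wy) * ((1 - wx) * MU(ix0, iy0, iz1) + wx * MU(ix1, iy0, iz1)) +
                  wy * ((1 - wx) * MU(ix0, iy1, iz1) + wx * MU(ix1, iy1, iz1)));
#undef MU
        po[(size_t)i + (size_t)mx * ((size_t)j + (size_t)my * k)] = v;
      }
    }
  }
  out.attr("dim") = newdims;
  return out;
}
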