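// Cone-beam ray-driven projector and voxel-driven back projector for a
// partial-isocentric tomosynthesis geometry: stationary detector in the
// z = 0 plane, X-ray source on an arc of radius `sid` about the detector
// centre, tube travel along the image column (x) axis.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Trilinear interpolation of mu at physical point (x,y,z); volume voxel
// centres are at origin + (i + 0.5) * voxel. Outside the grid -> 0.
// Points outside the physical volume contribute 0; inside, coordinates are
// clamped to the voxel-centre range so a uniform slab integrates exactly.
static inline double interp_mu(const double *mu, int nx, int ny, int nz,
                               double ox, double oy, double oz, double voxel,
                               double x, double y, double z) {
  if (x < ox || x > ox + nx * voxel || y < oy || y > oy + ny * voxel ||
      z < oz || z > oz + nz * voxel)
    return 0.0;
  double fx = std::min(std::max((x - ox) / voxel - 0.5, 0.0), nx - 1.0);
  double fy = std::min(std::max((y - oy) / voxel - 0.5, 0.0), ny - 1.0);
  double fz = std::min(std::max((z - oz) / voxel - 0.5, 0.0), nz - 1.0);
  int ix = std::min((int)fx, nx - 2 >= 0 ? nx - 2 : 0);
  int iy = std::min((int)fy, ny - 2 >= 0 ? ny - 2 : 0);
  int iz = std::min((int)fz, nz - 2 >= 0 ? nz - 2 : 0);
  double wx = fx - ix, wy = fy - iy, wz = fz - iz;
  int ix1 = std::min(ix + 1, nx - 1), iy1 = std::min(iy + 1, ny - 1),
      iz1 = std::min(iz + 1, nz - 1);
#define MU(a, b, c) mu[(size_t)(a) + (size_t)nx * ((size_t)(b) + (size_t)ny * (c))]
  double acc =
      (1 - wz) * ((1 - wy) * ((1 - wx) * MU(ix, iy, iz) + wx * MU(ix1, iy, iz)) +
                  wy * ((1 - wx) * MU(ix, iy1, iz) + wx * MU(ix1, iy1, iz))) +
      wz * ((1 - wy) * ((1 - wx) * MU(ix, iy, iz1) + wx * MU(ix1, iy, iz1)) +
            wy * ((1 - wx) * MU(ix, iy1, iz1) + wx * MU(ix1, iy1, iz1)));
#undef MU
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector mu, IntegerVector dims,
                                  double voxel, NumericVector origin,
                                  NumericVector angles, double sid,
                                  int det_rows, int det_cols, double pitch,
                                  double cx, double cy, double step_frac) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nv = angles.size();
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double ztop = oz + nz * voxel;
  const double step = voxel * step_frac;
  NumericVector out((size_t)det_rows * det_cols * nv);
  const double *pmu = REAL(mu);
  double *pout = REAL(out);

  for (int v = 0; v < nv; ++v) {
    const double sx = cx + sid * std::sin(angles[v]);
    const double sy = cy;
    const double sz = sid * std::cos(angles[v]);
    for (int c = 0; c < det_cols; ++c) {
      const double px = (c + 0.5) * pitch;
      for (int r = 0; r < det_rows; ++r) {
        const double py = (r + 0.5) * pitch;
        const double dx = px - sx, dy = py - sy, dz = 0.0 - sz;
        const double L = std::sqrt(dx * dx + dy * dy + dz * dz);
        // slab intersection in ray parameter t (0 at source, 1 at detector)
        double t0 = (oz - sz) / dz, t1 = (ztop - sz) / dz;
        if (t0 > t1) std::swap(t0, t1);
        t0 = std::max(t0, 0.0);
        t1 = std::min(t1, 1.0);
        double integ = 0.0;
        if (t1 > t0) {
          const double seg = (t1 - t0) * L;
          const int nstep = std::max(1, (int)std::ceil(seg / step));
          const double dt = (t1 - t0) / nstep;
          for (int k = 0; k < nstep; ++k) {
            const double t = t0 + (k + 0.5) * dt;
            integ += interp_mu(pmu, nx, ny, nz, ox, oy, oz, voxel,
                               sx + t * dx, sy + t * dy, sz + t * dz);
          }
          integ *= dt * L;
        }
        pout[(size_t)r + (size_t)det_rows * ((size_t)c + (size_t)det_cols * v)] = integ;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(det_rows, det_cols, nv);
  return out;
}

// Voxel-driven shift-and-add back projection onto slices at the requested
// heights. The reconstruction grid is the detector grid demagnified to each
// slice height and centred on the detector centre. Out-of-detector samples
// are excluded and the view average renormalized by the hit count.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector proj, IntegerVector pdims,
                              NumericVector angles, double sid, double pitch,
                              double cx, double cy, NumericVector heights) {
  const int rows = pdims[0], cols = pdims[1], nv = pdims[2];
  const int nh = heights.size();
  NumericVector out((size_t)rows * cols * nh);
  const double *pp = REAL(proj);
  double *po = REAL(out);

  for (int h = 0; h < nh; ++h) {
    const double z = heights[h];
    for (int v = 0; v < nv; ++v) {
      const double sx = cx + sid * std::sin(angles[v]);
      const double sy = cy;
      const double sz = sid * std::cos(angles[v]);
      const double s = sz / (sz - z);  // point -> detector perspective scale
      const double demag = (sid - z) / sid;
      const double ppx = pitch * demag;  // recon pixel pitch at height z
      for (int c = 0; c < cols; ++c) {
        const double x = cx + (c + 0.5 - cols * 0.5) * ppx;
        const double u = (sx + (x - sx) * s) / pitch - 0.5;  // detector col coord
        const int iu = (int)std::floor(u);
        if (iu < -1 || iu > cols - 1) continue;
        const double wu = u - iu;
        for (int r = 0; r < rows; ++r) {
          const double y = cy + (r + 0.5 - rows * 0.5) * ppx;
          const double w = (sy + (y - sy) * s) / pitch - 0.5;  // detector row coord
          const int iw = (int)std::floor(w);
          if (iw < -1 || iw > rows - 1) continue;
          const double ww = w - iw;
          double val = 0.0, wsum = 0.0;
          for (int du = 0; du <= 1; ++du) {
            const int cu = iu + du;
            if (cu < 0 || cu >= cols) continue;
            const double wu_ = du ? wu : 1.0 - wu;
            for (int dw = 0; dw <= 1; ++dw) {
              const int rw = iw + dw;
              if (rw < 0 || rw >= rows) continue;
              const double ww_ = dw ? ww : 1.0 - ww;
              val += wu_ * ww_ *
                     pp[(size_t)rw + (size_t)rows * ((size_t)cu + (size_t)cols * v)];
              wsum += wu_ * ww_;
            }
          }
          if (wsum > 0) {
            // store value and hit weight; hits accumulated in imaginary part
            // trick avoided: accumulate weighted value, weight in second pass
            po[(size_t)r + (size_t)rows * ((size_t)c + (size_t)cols * h)] += val;
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(rows, cols, nh);
  return out;
}

// Per-pixel hit counts matching cpp_backproject's sampling (a view "hits" a
// recon pixel when its detector sample has nonzero bilinear support).
// [[Rcpp::export]]
NumericVector cpp_backproject_hits(IntegerVector pdims, NumericVector angles,
                                   double sid, double pitch, double cx,
                                   double cy, NumericVector heights) {
  const int rows = pdims[0], cols = pdims[1], nv = pdims[2];
  const int nh = heights.size();
  NumericVector out((size_t)rows * cols * nh);
  double *po = REAL(out);
  for (int h = 0; h < nh; ++h) {
    const double z = heights[h];
    for (int v = 0; v < nv; ++v) {
      const double sx = cx + sid * std::sin(angles[v]);
      const double sy = cy;
      const double sz = sid * std::cos(angles[v]);
      const double s = sz / (sz - z);
      const double demag = (sid - z) / sid;
      const double ppx = pitch * demag;
      for (int c = 0; c < cols; ++c) {
        const double x = cx + (c + 0.5 - cols * 0.5) * ppx;
        const double u = (sx + (x - sx) * s) / pitch - 0.5;
        const int iu = (int)std::floor(u);
        if (iu < -1 || iu > cols - 1) continue;
        const double wu = u - iu;
        for (int r = 0; r < rows; ++r) {
          const double y = cy + (r + 0.5 - rows * 0.5) * ppx;
          const double w = (sy + (y - sy) * s) / pitch - 0.5;
          const int iw = (int)std::floor(w);
          if (iw < -1 || iw > rows - 1) continue;
          const double ww = w - iw;
          double wsum = 0.0;
          for (int du = 0; du <= 1; ++du) {
            const int cu = iu + du;
            if (cu < 0 || cu >= cols) continue;
            for (int dw = 0; dw <= 1; ++dw) {
              const int rw = iw + dw;
              if (rw < 0 || rw >= rows) continue;
              wsum += (du ? wu : 1.0 - wu) * (dw ? ww : 1.0 - ww);
            }
          }
          po[(size_t)r + (size_t)rows * ((size_t)c + (size_t)cols * h)] += wsum;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(rows, cols, nh);
  return out;
}
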