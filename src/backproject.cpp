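#include <Rcpp.h>
using namespace Rcpp;

// Voxel-driven FDK backprojection with optional per-view SI voxel shifting.
//
// filtered : nv x nu x n array of ramp-filtered projections
// P        : n x 12 matrix, each row a row-major 3x4 projection matrix
// sources  : n x 3 source positions (mm)
// axes     : n x 3 unit optical-axis directions (source -> isocenter)
// mtype    : 0 = constant shift (m1[i] mm per view),
//            1 = linear-in-z shift (m1 = scaled signal, m2 = diaphragm z,
//                m3 = z_max)
// Each reference-grid voxel is evaluated at its view-time position
// (shift applied before projection), sampled bilinearly and accumulated
// with weight dbeta * sod^2 / U^2.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector filtered, NumericMatrix P,
                              NumericMatrix sources, NumericMatrix axes,
                              double sod, double dbeta,
                              IntegerVector shape, NumericVector spacing,
                              NumericVector origin, int mtype,
                              NumericVector m1, NumericVector m2, double m3) {
  IntegerVector fdim = filtered.attr("dim");
  const int nv = fdim[0], nu = fdim[1], n = fdim[2];
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  NumericVector vol(static_cast<R_xlen_t>(nx) * ny * nz);
  vol.attr("dim") = IntegerVector::create(nx, ny, nz);

  const double *proj = filtered.begin();
  double *v = vol.begin();

  for (int i = 0; i < n; ++i) {
    const double *pr = &P(i, 0);  // column-major access handled below
    double p00 = P(i, 0), p01 = P(i, 1), p02 = P(i, 2), p03 = P(i, 3);
    double p10 = P(i, 4), p11 = P(i, 5), p12 = P(i, 6), p13 = P(i, 7);
    double p20 = P(i, 8), p21 = P(i, 9), p22 = P(i, 10), p23 = P(i, 11);
    (void)pr;
    double sx = sources(i, 0), sy = sources(i, 1), sz = sources(i, 2);
    double ax = axes(i, 0), ay = axes(i, 1), az = axes(i, 2);
    const double *page = proj + static_cast<R_xlen_t>(i) * nv * nu;
    double slope = 0.0;
    if (mtype == 1) slope = m1[i] / (m3 - m2[i]);

    R_xlen_t idx = 0;
    for (int kz = 0; kz < nz; ++kz) {
      double z = origin[2] + kz * spacing[2];
      double zq;
      if (mtype == 0) {
        zq = z - m1[i];
      } else {
        zq = (z <= m3) ? z - slope * (m3 - z) : z;
      }
      for (int ky = 0; ky < ny; ++ky) {
        double y = origin[1] + ky * spacing[1];
        // partial homogeneous coordinates for (., y, zq)
        double h0yz = p01 * y + p02 * zq + p03;
        double h1yz = p11 * y + p12 * zq + p13;
        double h2yz = p21 * y + p22 * zq + p23;
        double uyz = ay * (y - sy) + az * (zq - sz);
        for (int kx = 0; kx < nx; ++kx, ++idx) {
          double x = origin[0] + kx * spacing[0];
          double h2 = p20 * x + h2yz;
          if (h2 <= 1e-9) continue;
          double u = (p00 * x + h0yz) / h2;
          double vv = (p10 * x + h1yz) / h2;
          if (u < 0 || u > nu - 1 || vv < 0 || vv > nv - 1) continue;
          int iu = static_cast<int>(u);
          int iv = static_cast<int>(vv);
          if (iu >= nu - 1) iu = nu - 2;
          if (iv >= nv - 1) iv = nv - 2;
          double fu = u - iu, fv = vv - iv;
          const double *c0 = page + static_cast<R_xlen_t>(iu) * nv + iv;
          const double *c1 = c0 + nv;
          double val = (1 - fu) * ((1 - fv) * c0[0] + fv * c0[1]) +
                       fu * ((1 - fv) * c1[0] + fv * c1[1]);
          double U = ax * (x - sx) + uyz;
          double w = dbeta * sod * sod / (U * U);
          v[idx] += w * val;
        }
      }
    }
  }
  return vol;
}
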