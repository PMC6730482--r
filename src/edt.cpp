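#include <Rcpp.h>
#include <vector>
#include <limits>

// Exact squared Euclidean distance transform of a 3-D binary mask with
// anisotropic sample spacing, by the separable lower-envelope-of-parabolas
// pass applied along each axis in turn. Output: for every voxel, the squared
// world-mm distance from its center to the nearest foreground voxel center.

// One 1-D pass: d[q] = min_p ( (q*w - p*w)^2 + f[p] ). Sites with f = +inf
// carry no parabola and are excluded from the envelope; the caller skips
// lines with no finite site at all.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * w;
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    double s;
    for (;;) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k] && k > 0) { --k; continue; }
      break;
    }
    if (s <= z[k]) {        // k == 0 and the new parabola dominates everywhere
      v[0] = q;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = INF;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[kk + 1] < xq) ++kk;
    double dx = xq - v[kk] * w;
    d[q] = dx * dx + f[v[kk]];
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector edt_sq_cpp(Rcpp::LogicalVector mask,
                               Rcpp::IntegerVector dims,
                               Rcpp::NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 0 (stride 1)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      bool any = false;
      for (int i = 0; i < nx; ++i) {
        f[i] = out[base + i];
        if (f[i] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // axis 1 (stride nx)
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      bool any = false;
      for (int j = 0; j < ny; ++j) {
        f[j] = out[base + (R_xlen_t)nx * j];
        if (f[j] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // axis 2 (stride nx*ny)
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      bool any = false;
      for (int k = 0; k < nz; ++k) {
        f[k] = out[base + sxy * k];
        if (f[k] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + sxy * k] = d[k];
    }
  out.attr("dim") = dims;
  return out;
}
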