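#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (separable lower-envelope algorithm,
// Felzenszwalb & Huttenlocher 2012), generalized to anisotropic voxel
// spacing. Computes, for every voxel, the squared distance in mm^2 to the
// nearest "site" voxel center. Equivalent to Maurer's exact EDT.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double h) {
  const double INF = std::numeric_limits<double>::infinity();
  // build the lower envelope over positions with finite values only
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (!(f[q] < INF)) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      s = ((f[q] + h * h * q * q) - (f[v[k]] + h * h * v[k] * v[k])) /
          (2.0 * h * h * (q - v[k]));
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k]) { // displaced the only parabola
      v[k] = q; z[k] = -INF; z[k + 1] = INF;
    } else {
      ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
    }
  }
  if (k < 0) { // no finite values on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector sites, IntegerVector dim,
                         NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = sites[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = D[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) D[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = D[base + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = D[base + (R_xlen_t)k * nxy];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) D[base + (R_xlen_t)k * nxy] = d[k];
    }
  return D;
}

// ---------------------------------------------------------------------------
// Resample a 3D volume onto an output grid under an affine map of physical
// coordinates: y = A (x - c) + c + t, where x is the physical coordinate of
// an output voxel and y is looked up in the source volume.
// interp: 0 = nearest neighbor, 1 = trilinear. Outside -> outside_value.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector src, IntegerVector sdim,
                                  NumericVector sspacing, NumericVector sorigin,
                                  IntegerVector odim, NumericVector ospacing,
                                  NumericVector oorigin, NumericVector A,
                                  NumericVector tr, NumericVector cen,
                                  int interp, double outside_value,
                                  int clamp_border) {
  int snx = sdim[0], sny = sdim[1], snz = sdim[2];
  int onx = odim[0], ony = odim[1], onz = odim[2];
  R_xlen_t nout = (R_xlen_t)onx * ony * onz;
  NumericVector out(nout);
  R_xlen_t snxy = (R_xlen_t)snx * sny;
  double a11 = A[0], a12 = A[1], a13 = A[2];
  double a21 = A[3], a22 = A[4], a23 = A[5];
  double a31 = A[6], a32 = A[7], a33 = A[8];

  R_xlen_t idx = 0;
  for (int k = 0; k < onz; ++k) {
    double xz = oorigin[2] + k * ospacing[2] - cen[2];
    for (int j = 0; j < ony; ++j) {
      double xy = oorigin[1] + j * ospacing[1] - cen[1];
      for (int i = 0; i < onx; ++i, ++idx) {
        double xx = oorigin[0] + i * ospacing[0] - cen[0];
        double y0 = a11 * xx + a12 * xy + a13 * xz + cen[0] + tr[0];
        double y1 = a21 * xx + a22 * xy + a23 * xz + cen[1] + tr[1];
        double y2 = a31 * xx + a32 * xy + a33 * xz + cen[2] + tr[2];
        double u = (y0 - sorigin[0]) / sspacing[0];
        double v = (y1 - sorigin[1]) / sspacing[1];
        double w = (y2 - sorigin[2]) / sspacing[2];
        if (clamp_border) {
          if (u < 0) u = 0; if (u > snx - 1) u = snx - 1;
          if (v < 0) v = 0; if (v > sny - 1) v = sny - 1;
          if (w < 0) w = 0; if (w > snz - 1) w = snz - 1;
        }
        if (interp == 0) {
          int iu = (int)std::lround(u), iv = (int)std::lround(v),
              iw = (int)std::lround(w);
          if (iu < 0 || iu >= snx || iv < 0 || iv >= sny || iw < 0 || iw >= snz)
            out[idx] = outside_value;
          else
            out[idx] = src[(R_xlen_t)iw * snxy + (R_xlen_t)iv * snx + iu];
        } else {
          if (u < 0 || u > snx - 1 || v < 0 || v > sny - 1 ||
              w < 0 || w > snz - 1) {
            out[idx] = outside_value;
            continue;
          }
          int iu = (int)std::floor(u), iv = (int)std::floor(v),
              iw = (int)std::floor(w);
          if (iu == snx - 1) --iu;
          if (iv == sny - 1) --iv;
          if (iw == snz - 1) --iw;
          double fu = u - iu, fv = v - iv, fw = w - iw;
          R_xlen_t b000 = (R_xlen_t)iw * snxy + (R_xlen_t)iv * snx + iu;
          double c000 = src[b000],          c100 = src[b000 + 1];
          double c010 = src[b000 + snx],    c110 = src[b000 + snx + 1];
          double c001 = src[b000 + snxy],   c101 = src[b000 + snxy + 1];
          double c011 = src[b000 + snxy + snx], c111 = src[b000 + snxy + snx + 1];
          double c00 = c000 * (1 - fu) + c100 * fu;
          double c10 = c010 * (1 - fu) + c110 * fu;
          double c01 = c001 * (1 - fu) + c101 * fu;
          double c11 = c011 * (1 - fu) + c111 * fu;
          double c0 = c00 * (1 - fv) + c10 * fv;
          double c1 = c01 * (1 - fv) + c11 * fv;
          out[idx] = c0 * (1 - fw) + c1 * fw;
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Mean squared difference between fixed samples f(x_s) and the moving image
// interpolated at y_s = A (x_s - c) + c + t, plus its analytic gradient with
// respect to the 12 affine parameters (A row-major, then translation).
// Sample coordinates outside the moving domain are clamped to the border
// (distance maps extend smoothly, so clamping is benign for small motions).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_ssd_affine_grad(NumericVector mov, IntegerVector mdim,
                         NumericVector mspacing, NumericVector morigin,
                         NumericMatrix pts, NumericVector fvals,
                         NumericVector A, NumericVector tr,
                         NumericVector cen) {
  int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  int n = pts.nrow();
  double val = 0.0;
  NumericVector grad(12);
  double a11 = A[0], a12 = A[1], a13 = A[2];
  double a21 = A[3], a22 = A[4], a23 = A[5];
  double a31 = A[6], a32 = A[7], a33 = A[8];

  for (int s = 0; s < n; ++s) {
    double xx = pts(s, 0) - cen[0];
    double xy = pts(s, 1) - cen[1];
    double xz = pts(s, 2) - cen[2];
    double y0 = a11 * xx + a12 * xy + a13 * xz + cen[0] + tr[0];
    double y1 = a21 * xx + a22 * xy + a23 * xz + cen[1] + tr[1];
    double y2 = a31 * xx + a32 * xy + a33 * xz + cen[2] + tr[2];
    double u = (y0 - morigin[0]) / mspacing[0];
    double v = (y1 - morigin[1]) / mspacing[1];
    double w = (y2 - morigin[2]) / mspacing[2];
    if (u < 0) u = 0; if (u > nx - 1) u = nx - 1;
    if (v < 0) v = 0; if (v > ny - 1) v = ny - 1;
    if (w < 0) w = 0; if (w > nz - 1) w = nz - 1;
    int iu = (int)std::floor(u), iv = (int)std::floor(v),
        iw = (int)std::floor(w);
    if (iu == nx - 1) --iu;
    if (iv == ny - 1) --iv;
    if (iw == nz - 1) --iw;
    double fu = u - iu, fv = v - iv, fw = w - iw;
    R_xlen_t b000 = (R_xlen_t)iw * nxy + (R_xlen_t)iv * nx + iu;
    double c000 = mov[b000],            c100 = mov[b000 + 1];
    double c010 = mov[b000 + nx],       c110 = mov[b000 + nx + 1];
    double c001 = mov[b000 + nxy],      c101 = mov[b000 + nxy + 1];
    double c011 = mov[b000 + nxy + nx], c111 = mov[b000 + nxy + nx + 1];
    double c00 = c000 * (1 - fu) + c100 * fu;
    double c10 = c010 * (1 - fu) + c110 * fu;
    double c01 = c001 * (1 - fu) + c101 * fu;
    double c11 = c011 * (1 - fu) + c111 * fu;
    double c0 = c00 * (1 - fv) + c10 * fv;
    double c1 = c01 * (1 - fv) + c11 * fv;
    double m = c0 * (1 - fw) + c1 * fw;
    // partial derivatives of the trilinear value wrt continuous index
    double dmu = ((c100 - c000) * (1 - fv) + (c110 - c010) * fv) * (1 - fw) +
                 ((c101 - c001) * (1 - fv) + (c111 - c011) * fv) * fw;
    double dmv = (c10 - c00) * (1 - fw) + (c11 - c01) * fw;
    double dmw = c1 - c0;
    double gx = dmu / mspacing[0];
    double gy = dmv / mspacing[1];
    double gz = dmw / mspacing[2];
    double r = m - fvals[s];
    val += r * r;
    double w2 = 2.0 * r;
    grad[0] += w2 * gx * xx; grad[1] += w2 * gx * xy; grad[2] += w2 * gx * xz;
    grad[3] += w2 * gy * xx; grad[4] += w2 * gy * xy; grad[5] += w2 * gy * xz;
    grad[6] += w2 * gz * xx; grad[7] += w2 * gz * xy; grad[8] += w2 * gz * xz;
    grad[9] += w2 * gx; grad[10] += w2 * gy; grad[11] += w2 * gz;
  }
  val /= n;
  for (int q = 0; q < 12; ++q) grad[q] /= n;
  return List::create(Named("value") = val, Named("gradient") = grad);
}
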