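#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Continuous-index trilinear sampler. (x,y,z) are 0-based voxel coordinates.
// Values outside [0, n-1] on any axis return `fill`; a small tolerance keeps
// boundary voxels (coordinate == n-1 up to rounding) inside support.
static inline double tri_sample(const double* a, int nx, int ny, int nz,
                                double x, double y, double z, double fill) {
  const double eps = 1e-9;
  if (x < -eps || y < -eps || z < -eps ||
      x > nx - 1 + eps || y > ny - 1 + eps || z > nz - 1 + eps)
    return fill;
  if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
  if (x > nx - 1) x = nx - 1;
  if (y > ny - 1) y = ny - 1;
  if (z > nz - 1) z = nz - 1;
  int i0 = (int)std::floor(x); if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
  int j0 = (int)std::floor(y); if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
  int k0 = (int)std::floor(z); if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const double* p = a + i0 * sx + j0 * sy + k0 * sz;
  double c000 = p[0],      c100 = p[sx];
  double c010 = p[sy],     c110 = p[sx + sy];
  double c001 = p[sz],     c101 = p[sx + sz];
  double c011 = p[sy + sz], c111 = p[sx + sy + sz];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double nn_sample(const double* a, int nx, int ny, int nz,
                               double x, double y, double z, double fill) {
  const double eps = 1e-9;
  if (x < -0.5 - eps || y < -0.5 - eps || z < -0.5 - eps ||
      x > nx - 0.5 + eps || y > ny - 0.5 + eps || z > nz - 0.5 + eps)
    return fill;
  int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
  if (i < 0) i = 0; if (j < 0) j = 0; if (k < 0) k = 0;
  if (i > nx - 1) i = nx - 1; if (j > ny - 1) j = ny - 1; if (k > nz - 1) k = nz - 1;
  return a[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
}

// Resample src (geometry sp_s/org_s) onto the target grid (dim_t/sp_t/org_t).
// [[Rcpp::export]]
NumericVector c_resample(NumericVector src, IntegerVector dim_s,
                         NumericVector sp_s, NumericVector org_s,
                         IntegerVector dim_t, NumericVector sp_t,
                         NumericVector org_t, bool linear, double fill) {
  const int nx = dim_s[0], ny = dim_s[1], nz = dim_s[2];
  const int mx = dim_t[0], my = dim_t[1], mz = dim_t[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  const double* a = src.begin();
  double* o = out.begin();
  R_xlen_t idx = 0;
  for (int k = 0; k < mz; ++k) {
    double wz = org_t[2] + k * sp_t[2];
    double z = (wz - org_s[2]) / sp_s[2];
    for (int j = 0; j < my; ++j) {
      double wy = org_t[1] + j * sp_t[1];
      double y = (wy - org_s[1]) / sp_s[1];
      for (int i = 0; i < mx; ++i, ++idx) {
        double wx = org_t[0] + i * sp_t[0];
        double x = (wx - org_s[0]) / sp_s[0];
        o[idx] = linear ? tri_sample(a, nx, ny, nz, x, y, z, fill)
                        : nn_sample(a, nx, ny, nz, x, y, z, fill);
      }
    }
  }
  return out;
}

// Pull-back warp: out(x) = moving(x + u(x)); u given as three component
// volumes (mm) on the fixed grid.
// [[Rcpp::export]]
NumericVector c_warp(NumericVector mov, IntegerVector dim_m,
                     NumericVector sp_m, NumericVector org_m,
                     NumericVector ux, NumericVector uy, NumericVector uz,
                     IntegerVector dim_f, NumericVector sp_f,
                     NumericVector org_f, bool linear, double fill) {
  const int nx = dim_m[0], ny = dim_m[1], nz = dim_m[2];
  const int mx = dim_f[0], my = dim_f[1], mz = dim_f[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  const double* a = mov.begin();
  double* o = out.begin();
  const double *px = ux.begin(), *py = uy.begin(), *pz = uz.begin();
  R_xlen_t idx = 0;
  for (int k = 0; k < mz; ++k) {
    double wz0 = org_f[2] + k * sp_f[2];
    for (int j = 0; j < my; ++j) {
      double wy0 = org_f[1] + j * sp_f[1];
      for (int i = 0; i < mx; ++i, ++idx) {
        double wx = org_f[0] + i * sp_f[0] + px[idx];
        double wy = wy0 + py[idx];
        double wz = wz0 + pz[idx];
        double x = (wx - org_m[0]) / sp_m[0];
        double y = (wy - org_m[1]) / sp_m[1];
        double z = (wz - org_m[2]) / sp_m[2];
        o[idx] = linear ? tri_sample(a, nx, ny, nz, x, y, z, fill)
                        : nn_sample(a, nx, ny, nz, x, y, z, fill);
      }
    }
  }
  return out;
}

// Separable Gaussian smoothing, sigma in voxels per axis, replicate borders.
// [[Rcpp::export]]
NumericVector c_gauss3(NumericVector arr, IntegerVector dim, NumericVector sigma) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t ntot = (R_xlen_t)n[0] * n[1] * n[2];
  NumericVector out = clone(arr);
  std::vector<double> buf(ntot);
  const R_xlen_t stride[3] = {1, (R_xlen_t)n[0], (R_xlen_t)n[0] * n[1]};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    if (r < 1) r = 1;
    std::vector<double> kern(2 * r + 1);
    double tot = 0;
    for (int t = -r; t <= r; ++t) {
      kern[t + r] = std::exp(-0.5 * t * t / (s * s));
      tot += kern[t + r];
    }
    for (double& kv : kern) kv /= tot;
    const int na = n[ax];
    const R_xlen_t sa = stride[ax];
    // iterate over all lines along axis ax
    int b = (ax == 0) ? 1 : 0;
    int c = (ax == 2) ? 1 : 2;
    const int nb = n[b], nc = n[c];
    const R_xlen_t sb = stride[b], sc = stride[c];
    double* src = out.begin();
    for (int ic = 0; ic < nc; ++ic) {
      for (int ib = 0; ib < nb; ++ib) {
        R_xlen_t base = ib * sb + ic * sc;
        for (int ia = 0; ia < na; ++ia) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int q = ia + t;
            if (q < 0) q = 0;
            if (q > na - 1) q = na - 1;
            acc += kern[t + r] * src[base + q * sa];
          }
          buf[base + ia * sa] = acc;
        }
      }
    }
    std::copy(buf.begin(), buf.end(), out.begin());
  }
  return out;
}

// 6-connected component labelling of a logical mask; labels 1..K in
// first-encounter order (deterministic).
// [[Rcpp::export]]
IntegerVector c_cc3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  const int* m = mask.begin();
  int* L = lab.begin();
  std::vector<R_xlen_t> stack;
  int next = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t p0 = 0; p0 < ntot; ++p0) {
    if (!m[p0] || L[p0]) continue;
    ++next;
    L[p0] = next;
    stack.push_back(p0);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int k = (int)(p / sz);
      int j = (int)((p - k * sz) / sy);
      int i = (int)(p - k * sz - j * sy);
      if (i > 0 && m[p - sx] && !L[p - sx]) { L[p - sx] = next; stack.push_back(p - sx); }
      if (i < nx - 1 && m[p + sx] && !L[p + sx]) { L[p + sx] = next; stack.push_back(p + sx); }
      if (j > 0 && m[p - sy] && !L[p - sy]) { L[p - sy] = next; stack.push_back(p - sy); }
      if (j < ny - 1 && m[p + sy] && !L[p + sy]) { L[p + sy] = next; stack.push_back(p + sy); }
      if (k > 0 && m[p - sz] && !L[p - sz]) { L[p - sz] = next; stack.push_back(p - sz); }
      if (k < nz - 1 && m[p + sz] && !L[p + sz]) { L[p + sz] = next; stack.push_back(p + sz); }
    }
  }
  return lab;
}

// Spacing-aware gradient (central differences, one-sided at borders).
// Returns an (ntot x 3) matrix of d/dx, d/dy, d/dz in units of value/mm.
// [[Rcpp::export]]
NumericMatrix c_grad3(NumericVector arr, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericMatrix g(ntot, 3);
  const double* a = arr.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++p) {
        double gx, gy, gz;
        if (nx == 1) gx = 0;
        else if (i == 0) gx = (a[p + sx] - a[p]) / spacing[0];
        else if (i == nx - 1) gx = (a[p] - a[p - sx]) / spacing[0];
        else gx = (a[p + sx] - a[p - sx]) / (2 * spacing[0]);
        if (ny == 1) gy = 0;
        else if (j == 0) gy = (a[p + sy] - a[p]) / spacing[1];
        else if (j == ny - 1) gy = (a[p] - a[p - sy]) / spacing[1];
        else gy = (a[p + sy] - a[p - sy]) / (2 * spacing[1]);
        if (nz == 1) gz = 0;
        else if (k == 0) gz = (a[p + sz] - a[p]) / spacing[2];
        else if (k == nz - 1) gz = (a[p] - a[p - sz]) / spacing[2];
        else gz = (a[p + sz] - a[p - sz]) / (2 * spacing[2]);
        g(p, 0) = gx; g(p, 1) = gy; g(p, 2) = gz;
      }
    }
  }
  return g;
}

// Demons force update: du = diff * g / (|g|^2 + diff^2 / ms^2), capped at
// max_step (mm). Operates in place on three preallocated component vectors.
// [[Rcpp::export]]
List c_demons_force(NumericVector diff, NumericMatrix grad, double ms2,
                    double max_step) {
  R_xlen_t n = diff.size();
  NumericVector dx(n), dy(n), dz(n);
  const double* d = diff.begin();
  for (R_xlen_t p = 0; p < n; ++p) {
    double gx = grad(p, 0), gy = grad(p, 1), gz = grad(p, 2);
    double den = gx * gx + gy * gy + gz * gz + d[p] * d[p] / ms2;
    if (den < 1e-12) continue;
    double f = d[p] / den;
    double ux = f * gx, uy = f * gy, uz = f * gz;
    double len = std::sqrt(ux * ux + uy * uy + uz * uz);
    if (len > max_step) {
      double sc = max_step / len;
      ux *= sc; uy *= sc; uz *= sc;
    }
    dx[p] = ux; dy[p] = uy; dz[p] = uz;
  }
  return List::create(_["x"] = dx, _["y"] = dy, _["z"] = dz);
}
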