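#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher, separable
// lower-envelope of parabolas), anisotropic voxel spacing honoured.  Input is
// a feature indicator; output is squared distance in mm^2 to the nearest
// feature voxel centre.
// ---------------------------------------------------------------------------

static void edt_1d(std::vector<double> &f, std::vector<double> &d,
                   std::vector<int> &v, std::vector<double> &z,
                   int n, double h) {
  // f: squared distance so far at each site (finite, possibly very large);
  // h: spacing along this axis (mm).  Textbook lower-envelope scan.
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qh = q * h;
    double s = ((f[q] + qh * qh) - (f[v[k]] + (v[k] * h) * (v[k] * h))) /
               (2.0 * qh - 2.0 * v[k] * h);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + qh * qh) - (f[v[k]] + (v[k] * h) * (v[k] * h))) /
          (2.0 * qh - 2.0 * v[k] * h);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qh = q * h;
    while (z[k + 1] < qh) ++k;
    double diff = qh - v[k] * h;
    d[q] = f[v[k]] + diff * diff;
  }
}

// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dim,
                         NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // large finite stand-in for "no feature yet": beyond any attainable sq dist
  double ex = nx * spacing[0] + ny * spacing[1] + nz * spacing[2];
  const double BIG = 4.0 * ex * ex + 1.0;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = feature[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      edt_1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      edt_1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nx * ny];
      edt_1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nx * ny] = d[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Interpolation at continuous 0-based index coordinates.
// pts: n x 3 matrix of continuous voxel indices.  Out-of-field -> fill.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_interp3")]]
NumericVector cpp_interp3(NumericVector vol, IntegerVector dim,
                          NumericMatrix pts, double fill, bool nearest) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z)) { out[p] = fill; continue; }
    if (nearest) {
      long i = lround(x), j = lround(y), k = lround(z);
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) out[p] = fill;
      else out[p] = vol[i * sx + j * sy + k * sz];
    } else {
      if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
        out[p] = fill; continue;
      }
      int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
      if (i0 == nx - 1) --i0;
      if (j0 == ny - 1) --j0;
      if (k0 == nz - 1) --k0;
      if (nx == 1) i0 = 0;
      if (ny == 1) j0 = 0;
      if (nz == 1) k0 = 0;
      double fx = x - i0, fy = y - j0, fz = z - k0;
      int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
          k1 = std::min(k0 + 1, nz - 1);
      double c000 = vol[i0 * sx + j0 * sy + k0 * sz];
      double c100 = vol[i1 * sx + j0 * sy + k0 * sz];
      double c010 = vol[i0 * sx + j1 * sy + k0 * sz];
      double c110 = vol[i1 * sx + j1 * sy + k0 * sz];
      double c001 = vol[i0 * sx + j0 * sy + k1 * sz];
      double c101 = vol[i1 * sx + j0 * sy + k1 * sz];
      double c011 = vol[i0 * sx + j1 * sy + k1 * sz];
      double c111 = vol[i1 * sx + j1 * sy + k1 * sz];
      double c00 = c000 * (1 - fx) + c100 * fx;
      double c10 = c010 * (1 - fx) + c110 * fx;
      double c01 = c001 * (1 - fx) + c101 * fx;
      double c11 = c011 * (1 - fx) + c111 * fx;
      double c0 = c00 * (1 - fy) + c10 * fy;
      double c1 = c01 * (1 - fy) + c11 * fy;
      out[p] = c0 * (1 - fz) + c1 * fz;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Mattes MI core: joint Parzen histogram (zero-order fixed, cubic B-spline
// moving window), entropies, and the per-sample derivative of -MI with
// respect to the continuous moving-bin coordinate.
// ---------------------------------------------------------------------------

static inline double bsp3(double t) {
  double a = std::fabs(t);
  if (a >= 2.0) return 0.0;
  double w = (2.0 - a);
  w = w * w * w / 6.0;
  if (a < 1.0) {
    double u = (1.0 - a);
    w -= 4.0 * u * u * u / 6.0;
  }
  return w;
}

static inline double bsp3d(double t) {
  double a = std::fabs(t);
  if (a >= 2.0) return 0.0;
  double w = -(2.0 - a) * (2.0 - a) / 2.0;
  if (a < 1.0) {
    double u = (1.0 - a);
    w += 2.0 * u * u;
  }
  return (t >= 0) ? w : -w;
}

// fb: 0-based fixed bin per (valid) sample; mhat: continuous moving-bin
// coordinate, clamped to [1, nb-2).  Returns -MI and optionally d(-MI)/dmhat.
// [[Rcpp::export(name = ".cpp_mattes")]]
List cpp_mattes(IntegerVector fb, NumericVector mhat, int nb, bool deriv) {
  R_xlen_t n = fb.size();
  std::vector<double> P((size_t)nb * nb, 0.0);
  for (R_xlen_t i = 0; i < n; ++i) {
    int m0 = (int)std::floor(mhat[i]) - 1;
    double base = mhat[i] - m0;
    int f = fb[i];
    for (int k = 0; k < 4; ++k)
      P[(size_t)(m0 + k) * nb + f] += bsp3(base - k);
  }
  double invN = 1.0 / (double)n;
  std::vector<double> pf(nb, 0.0), pm(nb, 0.0);
  for (int m = 0; m < nb; ++m)
    for (int f = 0; f < nb; ++f) {
      double v = P[(size_t)m * nb + f] * invN;
      P[(size_t)m * nb + f] = v;
      pf[f] += v;
      pm[m] += v;
    }
  double mi = 0.0;
  for (int m = 0; m < nb; ++m)
    for (int f = 0; f < nb; ++f) {
      double v = P[(size_t)m * nb + f];
      if (v > 0) mi += v * std::log(v);
    }
  for (int f = 0; f < nb; ++f) if (pf[f] > 0) mi -= pf[f] * std::log(pf[f]);
  for (int m = 0; m < nb; ++m) if (pm[m] > 0) mi -= pm[m] * std::log(pm[m]);

  List out = List::create(Named("value") = -mi);
  if (deriv) {
    std::vector<double> logQ((size_t)nb * nb, 0.0); // log P(f,m) - log pm(m)
    for (int m = 0; m < nb; ++m)
      for (int f = 0; f < nb; ++f) {
        double v = P[(size_t)m * nb + f];
        logQ[(size_t)m * nb + f] =
          (v > 0 && pm[m] > 0) ? std::log(v) - std::log(pm[m]) : 0.0;
      }
    NumericVector d(n);
    for (R_xlen_t i = 0; i < n; ++i) {
      int m0 = (int)std::floor(mhat[i]) - 1;
      double base = mhat[i] - m0;
      int f = fb[i];
      double acc = 0.0;
      for (int k = 0; k < 4; ++k)
        acc += bsp3d(base - k) * logQ[(size_t)(m0 + k) * nb + f];
      d[i] = acc * invN;
    }
    out["dmhat"] = d;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling, 26-connectivity, iterative flood fill.
// Returns integer labels (0 = background), labelled in scan order.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_label26")]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      int k = idx / ((R_xlen_t)nx * ny);
      int rem = idx - (R_xlen_t)k * nx * ny;
      int j = rem / nx, i = rem - j * nx;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t q = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
            if (mask[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
          }
    }
  }
  return lab;
}
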