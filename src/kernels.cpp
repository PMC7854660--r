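// Low-level volumetric kernels. All volumes are R numeric 3D arrays in
// column-major (x, y, z) order; displacement fields are passed as three
// component arrays in voxel units of the grid they live on.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // symmetric reflection about the array edge: (-1 -> 0, -2 -> 1, n -> n-1, ...)
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  if (sigma <= 0) return std::vector<double>(1, 1.0);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  return k;
}

static inline int wrap_idx(int i, int n) {
  i %= n;
  return i < 0 ? i + n : i;
}

// Separable Gaussian blur; reflecting boundary by default, periodic when
// `wrap` (periodic keeps a stationary random field stationary).
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(NumericVector vol, IntegerVector dims,
                              NumericVector sigma, bool wrap = false) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const int strides[3] = {1, nx, nx * ny};
  const int sizes[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    if (sigma[ax] <= 0) continue;
    std::vector<double> k = gauss_kernel(sigma[ax]);
    int r = ((int)k.size() - 1) / 2;
    int nax = sizes[ax], st = strides[ax];
    // iterate over all lines along axis ax
    int n1 = sizes[(ax + 1) % 3], n2 = sizes[(ax + 2) % 3];
    int st1 = strides[(ax + 1) % 3], st2 = strides[(ax + 2) % 3];
    for (int i2 = 0; i2 < n2; ++i2) {
      for (int i1 = 0; i1 < n1; ++i1) {
        R_xlen_t base = (R_xlen_t)i1 * st1 + (R_xlen_t)i2 * st2;
        for (int i = 0; i < nax; ++i) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j) {
            int ii = wrap ? wrap_idx(i + j, nax) : reflect_idx(i + j, nax);
            acc += k[j + r] * a[base + (R_xlen_t)ii * st];
          }
          b[base + (R_xlen_t)i * st] = acc;
        }
      }
    }
    std::swap(a, b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Catmull-Rom cubic weight
static inline void cubic_w(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2 * t2 - t);
  w[1] = 0.5 * (3 * t3 - 5 * t2 + 2);
  w[2] = 0.5 * (-3 * t3 + 4 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

static inline int clampi(int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); }

static double sample3(const double *a, int nx, int ny, int nz,
                      double x, double y, double z, bool cubic) {
  if (!cubic) {
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double acc = 0.0;
    for (int dz = 0; dz <= 1; ++dz)
      for (int dy = 0; dy <= 1; ++dy)
        for (int dx = 0; dx <= 1; ++dx) {
          double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
          if (w == 0.0) continue;
          acc += w * a[(R_xlen_t)clampi(x0 + dx, nx) +
                       (R_xlen_t)nx * (clampi(y0 + dy, ny) +
                       (R_xlen_t)ny * clampi(z0 + dz, nz))];
        }
    return acc;
  }
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double wx[4], wy[4], wz[4];
  cubic_w(x - x0, wx); cubic_w(y - y0, wy); cubic_w(z - z0, wz);
  double acc = 0.0;
  for (int dz = -1; dz <= 2; ++dz) {
    int zi = clampi(z0 + dz, nz);
    for (int dy = -1; dy <= 2; ++dy) {
      int yi = clampi(y0 + dy, ny);
      double wyz = wy[dy + 1] * wz[dz + 1];
      for (int dx = -1; dx <= 2; ++dx) {
        acc += wx[dx + 1] * wyz *
          a[(R_xlen_t)clampi(x0 + dx, nx) + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
      }
    }
  }
  return acc;
}

// Pull-back warp: out(x) = vol(x + u(x)); samples falling outside the grid
// give 0 and inside = 0. Field components in voxels.
// [[Rcpp::export]]
List cpp_warp3(NumericVector vol, IntegerVector dims,
               NumericVector ux, NumericVector uy, NumericVector uz,
               bool cubic) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  IntegerVector inside(n);
  const double *a = REAL(vol);
  R_xlen_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        double sx = x + ux[idx], sy = y + uy[idx], sz = z + uz[idx];
        if (sx < 0 || sx > nx - 1 || sy < 0 || sy > ny - 1 ||
            sz < 0 || sz > nz - 1) {
          out[idx] = 0.0; inside[idx] = 0;
        } else {
          out[idx] = sample3(a, nx, ny, nz, sx, sy, sz, cubic);
          inside[idx] = 1;
        }
      }
  out.attr("dim") = dims;
  inside.attr("dim") = dims;
  return List::create(_["data"] = out, _["inside"] = inside);
}

// Resample to new_dims; voxel centers aligned so that physical extent is
// preserved (out coordinate i maps to (i + 0.5) * n_src / n_dst - 0.5).
// [[Rcpp::export]]
NumericVector cpp_resize3(NumericVector vol, IntegerVector dims,
                          IntegerVector new_dims, bool cubic) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = new_dims[0], my = new_dims[1], mz = new_dims[2];
  const double fx = (double)nx / mx, fy = (double)ny / my, fz = (double)nz / mz;
  NumericVector out((R_xlen_t)mx * my * mz);
  const double *a = REAL(vol);
  R_xlen_t idx = 0;
  for (int z = 0; z < mz; ++z) {
    double sz = clampd((z + 0.5) * fz - 0.5, 0, nz - 1);
    for (int y = 0; y < my; ++y) {
      double sy = clampd((y + 0.5) * fy - 0.5, 0, ny - 1);
      for (int x = 0; x < mx; ++x, ++idx) {
        double sx = clampd((x + 0.5) * fx - 0.5, 0, nx - 1);
        out[idx] = sample3(a, nx, ny, nz, sx, sy, sz, cubic);
      }
    }
  }
  out.attr("dim") = new_dims;
  return out;
}

// Cube median filter with reflecting boundary.
// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector vol, IntegerVector dims, int size) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int r = size / 2;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double *a = REAL(vol);
  const int m = size * size * size;
  std::vector<double> buf(m);
  R_xlen_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        int k = 0;
        for (int dz = -r; dz <= r; ++dz) {
          int zi = reflect_idx(z + dz, nz);
          for (int dy = -r; dy <= r; ++dy) {
            int yi = reflect_idx(y + dy, ny);
            for (int dx = -r; dx <= r; ++dx)
              buf[k++] = a[(R_xlen_t)reflect_idx(x + dx, nx) +
                           (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        out[idx] = buf[m / 2];
      }
  out.attr("dim") = dims;
  return out;
}

// 26-connected component labelling (labels 1..k in order of first voxel
// encountered in column-major scan, so label 1 contains the lexicographically
// smallest voxel of its component).
// [[Rcpp::export]]
IntegerVector cpp_label3(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x = (int)(cur % nx), y = (int)((cur / nx) % ny), z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        int zi = z + dz; if (zi < 0 || zi >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yi = y + dy; if (yi < 0 || yi >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xi = x + dx; if (xi < 0 || xi >= nx) continue;
            R_xlen_t q = (R_xlen_t)xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi);
            if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// One pyramid level of Thirion demons. Updates the field in place-semantics:
// takes the incoming field (voxel units of this level) and returns the
// refined field after `iters` iterations. The accumulated field is smoothed
// with a Gaussian of width `sigma` voxels after every iteration.
// [[Rcpp::export]]
List cpp_demons_level(NumericVector fixed, NumericVector moving,
                      IntegerVector dims, int iters, double sigma,
                      NumericVector ux0, NumericVector uy0, NumericVector uz0,
                      bool symmetric) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double *F = REAL(fixed);
  const double *M = REAL(moving);
  std::vector<double> ux(ux0.begin(), ux0.end());
  std::vector<double> uy(uy0.begin(), uy0.end());
  std::vector<double> uz(uz0.begin(), uz0.end());

  // fixed-image gradient (central differences), precomputed once
  std::vector<double> gx(n), gy(n), gz(n);
  {
    R_xlen_t idx = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++idx) {
          int xm = clampi(x - 1, nx), xp = clampi(x + 1, nx);
          int ym = clampi(y - 1, ny), yp = clampi(y + 1, ny);
          int zm = clampi(z - 1, nz), zp = clampi(z + 1, nz);
          gx[idx] = 0.5 * (F[(R_xlen_t)xp + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] -
                           F[(R_xlen_t)xm + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)]);
          gy[idx] = 0.5 * (F[(R_xlen_t)x + (R_xlen_t)nx * (yp + (R_xlen_t)ny * z)] -
                           F[(R_xlen_t)x + (R_xlen_t)nx * (ym + (R_xlen_t)ny * z)]);
          gz[idx] = 0.5 * (F[(R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * zp)] -
                           F[(R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * zm)]);
        }
  }

  std::vector<double> k = gauss_kernel(sigma);
  const int r = ((int)k.size() - 1) / 2;
  std::vector<double> tmp(n), tmp2(n);
  const int strides[3] = {1, nx, nx * ny};
  const int sizes[3] = {nx, ny, nz};
  auto smooth = [&](std::vector<double> &f) {
    if (sigma <= 0) return;
    for (int ax = 0; ax < 3; ++ax) {
      int nax = sizes[ax], st = strides[ax];
      int n1 = sizes[(ax + 1) % 3], n2 = sizes[(ax + 2) % 3];
      int st1 = strides[(ax + 1) % 3], st2 = strides[(ax + 2) % 3];
      for (int i2 = 0; i2 < n2; ++i2)
        for (int i1 = 0; i1 < n1; ++i1) {
          R_xlen_t base = (R_xlen_t)i1 * st1 + (R_xlen_t)i2 * st2;
          for (int i = 0; i < nax; ++i) {
            double acc = 0.0;
            for (int j = -r; j <= r; ++j)
              acc += k[j + r] * f[base + (R_xlen_t)reflect_idx(i + j, nax) * st];
            tmp[base + (R_xlen_t)i * st] = acc;
          }
        }
      std::swap(f, tmp);
    }
  };

  std::vector<double> mw(n);
  for (int it = 0; it < iters; ++it) {
    // warp the moving image by the current field (trilinear, clamped)
    R_xlen_t idx = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++idx) {
          double sx = clampd(x + ux[idx], 0, nx - 1);
          double sy = clampd(y + uy[idx], 0, ny - 1);
          double sz = clampd(z + uz[idx], 0, nz - 1);
          mw[idx] = sample3(M, nx, ny, nz, sx, sy, sz, false);
        }
    idx = 0;
    for (int z = 0; z < nz; ++z) {
      int zm = clampi(z - 1, nz), zp = clampi(z + 1, nz);
      for (int y = 0; y < ny; ++y) {
        int ym = clampi(y - 1, ny), yp = clampi(y + 1, ny);
        for (int x = 0; x < nx; ++x, ++idx) {
          double diff = mw[idx] - F[idx];
          double hx = gx[idx], hy = gy[idx], hz = gz[idx];
          if (symmetric) {
            // average with the central-difference gradient of the warped image
            int xm = clampi(x - 1, nx), xp = clampi(x + 1, nx);
            hx = 0.5 * (hx + 0.5 * (mw[(R_xlen_t)xp + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] -
                                    mw[(R_xlen_t)xm + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)]));
            hy = 0.5 * (hy + 0.5 * (mw[(R_xlen_t)x + (R_xlen_t)nx * (yp + (R_xlen_t)ny * z)] -
                                    mw[(R_xlen_t)x + (R_xlen_t)nx * (ym + (R_xlen_t)ny * z)]));
            hz = 0.5 * (hz + 0.5 * (mw[(R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * zp)] -
                                    mw[(R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * zm)]));
          }
          double g2 = hx * hx + hy * hy + hz * hz;
          double den = g2 + diff * diff;
          if (den > 1e-12) {
            double s = diff / den;
            ux[idx] -= s * hx;
            uy[idx] -= s * hy;
            uz[idx] -= s * hz;
          }
        }
      }
    }
    smooth(ux); smooth(uy); smooth(uz);
  }

  NumericVector oux(n), ouy(n), ouz(n);
  std::copy(ux.begin(), ux.end(), oux.begin());
  std::copy(uy.begin(), uy.end(), ouy.begin());
  std::copy(uz.begin(), uz.end(), ouz.begin());
  oux.attr("dim") = dims; ouy.attr("dim") = dims; ouz.attr("dim") = dims;
  return List::create(_["ux"] = oux, _["uy"] = ouy, _["uz"] = ouz);
}
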