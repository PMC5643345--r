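#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Volumes are R arrays with dim = c(nz, ny, nx): linear index z + nz*(y + ny*x).
// z is the tomographic rotation axis; rotations act in the (y, x) plane.

static inline R_xlen_t vidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// Parallel-beam line integrals of `vol` at `angles` (radians).
// For angle th and detector coordinate t (voxel units, centred), the ray is
//   x(s) = cx + t*cos(th) - s*sin(th),  y(s) = cy + t*sin(th) + s*cos(th)
// sampled at unit (voxel) steps with bilinear interpolation; samples outside
// the grid contribute zero. Output dim = c(nz, nt, n_angles), values in
// voxel-length units (caller multiplies by the physical voxel size).
// [[Rcpp::export]]
NumericVector cpp_radon(NumericVector vol, IntegerVector dim, NumericVector angles) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int na = angles.size();
  const int nt = nx;
  const double cy = 0.5 * (ny - 1), cx = 0.5 * (nx - 1);
  const double ct = 0.5 * (nt - 1);
  const double diag = std::sqrt((double)nx * nx + (double)ny * ny);
  const int ns = (int)std::ceil(diag) + 3;
  const double s0 = -0.5 * (ns - 1);

  NumericVector out((R_xlen_t)nz * nt * na);
  out.attr("dim") = IntegerVector::create(nz, nt, na);
  const double* v = REAL(vol);
  double* o = REAL(out);

  for (int a = 0; a < na; ++a) {
    const double c = std::cos(angles[a]), sn = std::sin(angles[a]);
    for (int j = 0; j < nt; ++j) {
      const double t = j - ct;
      double* col = o + (R_xlen_t)nz * ((R_xlen_t)j + (R_xlen_t)nt * a);
      for (int k = 0; k < ns; ++k) {
        const double s = s0 + k;
        const double x = cx + t * c - s * sn;
        const double y = cy + t * sn + s * c;
        const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
        if (x0 < -1 || x0 > nx - 1 || y0 < -1 || y0 > ny - 1) continue;
        const double fx = x - x0, fy = y - y0;
        const double w00 = (1 - fy) * (1 - fx), w10 = fy * (1 - fx);
        const double w01 = (1 - fy) * fx, w11 = fy * fx;
        const bool ix0 = x0 >= 0 && x0 < nx, ix1 = x0 + 1 >= 0 && x0 + 1 < nx;
        const bool iy0 = y0 >= 0 && y0 < ny, iy1 = y0 + 1 >= 0 && y0 + 1 < ny;
        const double* p00 = (iy0 && ix0) ? v + vidx(0, y0, x0, nz, ny) : 0;
        const double* p10 = (iy1 && ix0) ? v + vidx(0, y0 + 1, x0, nz, ny) : 0;
        const double* p01 = (iy0 && ix1) ? v + vidx(0, y0, x0 + 1, nz, ny) : 0;
        const double* p11 = (iy1 && ix1) ? v + vidx(0, y0 + 1, x0 + 1, nz, ny) : 0;
        for (int z = 0; z < nz; ++z) {
          double acc = 0.0;
          if (p00) acc += w00 * p00[z];
          if (p10) acc += w10 * p10[z];
          if (p01) acc += w01 * p01[z];
          if (p11) acc += w11 * p11[z];
          col[z] += acc;
        }
      }
    }
  }
  return out;
}

// Backprojection adjoint to cpp_radon. `sino` dim = c(nz, nt, na); output
// dim = c(nz, ny, nx). Caller applies the pi/n_angles FBP weighting.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector sino, IntegerVector dim,
                              NumericVector angles, int ny, int nx) {
  const int nz = dim[0], nt = dim[1];
  const int na = angles.size();
  const double cy = 0.5 * (ny - 1), cx = 0.5 * (nx - 1), ct = 0.5 * (nt - 1);

  NumericVector out((R_xlen_t)nz * ny * nx);
  out.attr("dim") = IntegerVector::create(nz, ny, nx);
  double* o = REAL(out);
  const double* s = REAL(sino);

  for (int a = 0; a < na; ++a) {
    const double c = std::cos(angles[a]), sn = std::sin(angles[a]);
    const double* sa = s + (R_xlen_t)nz * (R_xlen_t)nt * a;
    for (int x = 0; x < nx; ++x) {
      const double dx = (x - cx) * c;
      for (int y = 0; y < ny; ++y) {
        const double t = dx + (y - cy) * sn + ct;
        const int j0 = (int)std::floor(t);
        if (j0 < -1 || j0 > nt - 1) continue;
        const double f = t - j0;
        const double* c0 = (j0 >= 0) ? sa + (R_xlen_t)nz * j0 : 0;
        const double* c1 = (j0 + 1 < nt) ? sa + (R_xlen_t)nz * (j0 + 1) : 0;
        double* oc = o + vidx(0, y, x, nz, ny);
        if (c0 && c1) {
          const double w0 = 1 - f, w1 = f;
          for (int z = 0; z < nz; ++z) oc[z] += w0 * c0[z] + w1 * c1[z];
        } else if (c0) {
          const double w0 = 1 - f;
          for (int z = 0; z < nz; ++z) oc[z] += w0 * c0[z];
        } else if (c1) {
          for (int z = 0; z < nz; ++z) oc[z] += f * c1[z];
        }
      }
    }
  }
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), helper.
static void dt1d(const double* f, double* d, int n, int* v, double* zb) {
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double sp;
    while (true) {
      sp = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) / (2.0 * (q - v[k]));
      if (sp <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = sp;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in voxel units) from every voxel to the nearest
// TRUE voxel of `mask`. Voxels outside the volume are not feature voxels.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double INF = 1e30;
  NumericVector out(n);
  out.attr("dim") = dim;
  double* g = REAL(out);
  const int* m = LOGICAL(mask);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = (m[i] == TRUE) ? 0.0 : INF;

  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // along z (contiguous)
  for (R_xlen_t col = 0; col < (R_xlen_t)ny * nx; ++col) {
    double* p = g + col * nz;
    dt1d(p, d.data(), nz, v.data(), zb.data());
    std::copy(d.begin(), d.begin() + nz, p);
  }
  // along y
  for (int x = 0; x < nx; ++x) {
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = g[vidx(z, y, x, nz, ny)];
      dt1d(f.data(), d.data(), ny, v.data(), zb.data());
      for (int y = 0; y < ny; ++y) g[vidx(z, y, x, nz, ny)] = d[y];
    }
  }
  // along x
  for (int y = 0; y < ny; ++y) {
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = g[vidx(z, y, x, nz, ny)];
      dt1d(f.data(), d.data(), nx, v.data(), zb.data());
      for (int x = 0; x < nx; ++x) g[vidx(z, y, x, nz, ny)] = d[x];
    }
  }
  return out;
}

// Connected-component labelling of a logical volume, connectivity 6 or 26.
// Labels are 1..n_components in first-encounter order; background is 0.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector out(n);
  out.attr("dim") = dim;
  int* lab = INTEGER(out);
  const int* m = LOGICAL(mask);

  std::vector<int> dz, dy, dx;
  for (int az = -1; az <= 1; ++az)
    for (int ay = -1; ay <= 1; ++ay)
      for (int ax = -1; ax <= 1; ++ax) {
        if (az == 0 && ay == 0 && ax == 0) continue;
        const int manh = std::abs(az) + std::abs(ay) + std::abs(ax);
        if (connectivity == 6 && manh != 1) continue;
        dz.push_back(az); dy.push_back(ay); dx.push_back(ax);
      }
  const int nb = dz.size();

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const R_xlen_t i = vidx(z, y, x, nz, ny);
        if (m[i] != TRUE || lab[i] != 0) continue;
        lab[i] = ++next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          const R_xlen_t cur = stack.back();
          stack.pop_back();
          const int cx2 = (int)(cur / ((R_xlen_t)nz * ny));
          const int rem = (int)(cur - (R_xlen_t)cx2 * nz * ny);
          const int cy2 = rem / nz, cz2 = rem % nz;
          for (int k = 0; k < nb; ++k) {
            const int zz = cz2 + dz[k], yy = cy2 + dy[k], xx = cx2 + dx[k];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            const R_xlen_t q = vidx(zz, yy, xx, nz, ny);
            if (m[q] == TRUE && lab[q] == 0) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
        }
      }
  return out;
}

// Local thickness: for each TRUE voxel, the diameter (voxel units) of the
// largest sphere that contains it while fitting inside the mask. `edt_sq`
// is cpp_edt_sq(!mask) evaluated on the complement, i.e. squared distance to
// the nearest background voxel. Sphere-painting over all mask voxels, with
// a cheap dominance skip (a voxel whose sphere lies inside a face-neighbour's
// sphere cannot contribute the maximum).
// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector edt_sq, LogicalVector mask,
                                  IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  out.attr("dim") = dim;
  double* o = REAL(out);
  const double* e = REAL(edt_sq);
  const int* m = LOGICAL(mask);

  const int fdz[6] = {1, -1, 0, 0, 0, 0};
  const int fdy[6] = {0, 0, 1, -1, 0, 0};
  const int fdx[6] = {0, 0, 0, 0, 1, -1};

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const R_xlen_t i = vidx(z, y, x, nz, ny);
        if (m[i] != TRUE) continue;
        const double r2 = e[i];
        if (r2 <= 0) continue;
        const double r = std::sqrt(r2);
        bool dominated = false;
        for (int k = 0; k < 6; ++k) {
          const int zz = z + fdz[k], yy = y + fdy[k], xx = x + fdx[k];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          const R_xlen_t q = vidx(zz, yy, xx, nz, ny);
          if (m[q] == TRUE && std::sqrt(e[q]) >= r + 1.0) { dominated = true; break; }
        }
        if (dominated) continue;
        const int ri = (int)std::floor(r);
        const double d2 = 4.0 * r2;  // squared diameter
        for (int ax = std::max(0, x - ri); ax <= std::min(nx - 1, x + ri); ++ax) {
          const double qx = (double)(ax - x) * (ax - x);
          for (int ay = std::max(0, y - ri); ay <= std::min(ny - 1, y + ri); ++ay) {
            const double qxy = qx + (double)(ay - y) * (ay - y);
            if (qxy > r2) continue;
            const int zr = (int)std::floor(std::sqrt(r2 - qxy));
            double* oc = o + vidx(0, ay, ax, nz, ny);
            for (int az = std::max(0, z - zr); az <= std::min(nz - 1, z + zr); ++az)
              if (oc[az] < d2) oc[az] = d2;
          }
        }
      }
  for (R_xlen_t i = 0; i < n; ++i) o[i] = (m[i] == TRUE) ? std::sqrt(o[i]) : 0.0;
  return out;
}

// Labels (26-adjacency) that touch any TRUE voxel of `outside`.
// [[Rcpp::export]]
IntegerVector cpp_touching_labels(IntegerVector labels, LogicalVector outside,
                                  IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int* lab = INTEGER(labels);
  const int* o = LOGICAL(outside);
  int maxlab = 0;
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  for (R_xlen_t i = 0; i < n; ++i) if (lab[i] > maxlab) maxlab = lab[i];
  std::vector<char> hit(maxlab + 1, 0);

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const R_xlen_t i = vidx(z, y, x, nz, ny);
        const int L = lab[i];
        if (L == 0 || hit[L]) continue;
        for (int az = -1; az <= 1 && !hit[L]; ++az)
          for (int ay = -1; ay <= 1 && !hit[L]; ++ay)
            for (int ax = -1; ax <= 1; ++ax) {
              const int zz = z + az, yy = y + ay, xx = x + ax;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
              if (o[vidx(zz, yy, xx, nz, ny)] == TRUE) { hit[L] = 1; break; }
            }
      }
  std::vector<int> res;
  for (int L = 1; L <= maxlab; ++L) if (hit[L]) res.push_back(L);
  return wrap(res);
}
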