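#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Array layout throughout: column-major R arrays dim (nx, ny, nz, channels),
// flat index x + nx*(y + ny*(z + nz*c)).
// Conv weights: dim (3,3,3, c_in, c_out); transposed-conv weights: (2,2,2, c_in, c_out).

static inline size_t IDX3(int x, int y, int z, int nx, int ny) {
  return (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * (size_t)z);
}

// ---- 3x3x3 convolution, zero padding 1, stride 1 or 2 ----------------------

// [[Rcpp::export]]
NumericVector cp_conv3d_fw(NumericVector x, IntegerVector xd,
                           NumericVector w, NumericVector b, int stride) {
  int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3];
  int co = b.size();
  int ox = (nx - 1) / stride + 1, oy = (ny - 1) / stride + 1, oz = (nz - 1) / stride + 1;
  size_t osp = (size_t)ox * oy * oz, isp = (size_t)nx * ny * nz;
  NumericVector out((R_xlen_t)(osp * co));
  double *O = REAL(out), *X = REAL(x), *W = REAL(w);
  for (int c = 0; c < co; ++c) {
    double *Oc = O + osp * c, bc = b[c];
    for (size_t i = 0; i < osp; ++i) Oc[i] = bc;
  }
  for (int c = 0; c < co; ++c) {
    double *Oc = O + osp * c;
    for (int ic = 0; ic < ci; ++ic) {
      double *Xc = X + isp * ic;
      for (int kz = 0; kz < 3; ++kz)
      for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        double wv = W[kx + 3 * (ky + 3 * (kz + 3 * (ic + (size_t)ci * c)))];
        if (wv == 0.0) continue;
        for (int z = 0; z < oz; ++z) {
          int iz = z * stride + kz - 1; if (iz < 0 || iz >= nz) continue;
          for (int y = 0; y < oy; ++y) {
            int iy = y * stride + ky - 1; if (iy < 0 || iy >= ny) continue;
            double *Orow = Oc + (size_t)ox * (y + (size_t)oy * z);
            double *Xrow = Xc + (size_t)nx * (iy + (size_t)ny * iz);
            for (int xo = 0; xo < ox; ++xo) {
              int ix = xo * stride + kx - 1;
              if (ix >= 0 && ix < nx) Orow[xo] += wv * Xrow[ix];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, co);
  return out;
}

// [[Rcpp::export]]
List cp_conv3d_bw(NumericVector x, IntegerVector xd,
                  NumericVector w, NumericVector gout, int stride) {
  int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3];
  int ox = (nx - 1) / stride + 1, oy = (ny - 1) / stride + 1, oz = (nz - 1) / stride + 1;
  int co = (int)(gout.size() / ((size_t)ox * oy * oz));
  size_t osp = (size_t)ox * oy * oz, isp = (size_t)nx * ny * nz;
  NumericVector gx((R_xlen_t)(isp * ci)), gw(w.size()), gb(co);
  double *GX = REAL(gx), *GW = REAL(gw), *GB = REAL(gb);
  double *X = REAL(x), *W = REAL(w), *GO = REAL(gout);
  for (int c = 0; c < co; ++c) {
    double *Gc = GO + osp * c, s = 0.0;
    for (size_t i = 0; i < osp; ++i) s += Gc[i];
    GB[c] = s;
  }
  for (int c = 0; c < co; ++c) {
    double *Gc = GO + osp * c;
    for (int ic = 0; ic < ci; ++ic) {
      double *Xc = X + isp * ic, *GXc = GX + isp * ic;
      for (int kz = 0; kz < 3; ++kz)
      for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        size_t wi = kx + 3 * (ky + 3 * (kz + 3 * (ic + (size_t)ci * c)));
        double wv = W[wi], acc = 0.0;
        for (int z = 0; z < oz; ++z) {
          int iz = z * stride + kz - 1; if (iz < 0 || iz >= nz) continue;
          for (int y = 0; y < oy; ++y) {
            int iy = y * stride + ky - 1; if (iy < 0 || iy >= ny) continue;
            double *Grow = Gc + (size_t)ox * (y + (size_t)oy * z);
            double *Xrow = Xc + (size_t)nx * (iy + (size_t)ny * iz);
            double *GXrow = GXc + (size_t)nx * (iy + (size_t)ny * iz);
            for (int xo = 0; xo < ox; ++xo) {
              int ix = xo * stride + kx - 1;
              if (ix < 0 || ix >= nx) continue;
              double g = Grow[xo];
              acc += g * Xrow[ix];
              GXrow[ix] += g * wv;
            }
          }
        }
        GW[wi] = acc;
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, ci);
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---- transposed convolution, kernel 2, stride 2 (up-convolution) -----------

// [[Rcpp::export]]
NumericVector cp_convt3d_fw(NumericVector x, IntegerVector xd,
                            NumericVector w, NumericVector b) {
  int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3];
  int co = b.size();
  int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  size_t osp = (size_t)ox * oy * oz, isp = (size_t)nx * ny * nz;
  NumericVector out((R_xlen_t)(osp * co));
  double *O = REAL(out), *X = REAL(x), *W = REAL(w);
  for (int c = 0; c < co; ++c) {
    double *Oc = O + osp * c, bc = b[c];
    for (size_t i = 0; i < osp; ++i) Oc[i] = bc;
  }
  for (int c = 0; c < co; ++c) {
    double *Oc = O + osp * c;
    for (int ic = 0; ic < ci; ++ic) {
      double *Xc = X + isp * ic;
      for (int kz = 0; kz < 2; ++kz)
      for (int ky = 0; ky < 2; ++ky)
      for (int kx = 0; kx < 2; ++kx) {
        double wv = W[kx + 2 * (ky + 2 * (kz + 2 * (ic + (size_t)ci * c)))];
        if (wv == 0.0) continue;
        for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
          double *Orow = Oc + (size_t)ox * ((2 * y + ky) + (size_t)oy * (2 * z + kz));
          double *Xrow = Xc + (size_t)nx * (y + (size_t)ny * z);
          for (int xv = 0; xv < nx; ++xv) Orow[2 * xv + kx] += wv * Xrow[xv];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, co);
  return out;
}

// [[Rcpp::export]]
List cp_convt3d_bw(NumericVector x, IntegerVector xd,
                   NumericVector w, NumericVector gout) {
  int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3];
  int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  int co = (int)(gout.size() / ((size_t)ox * oy * oz));
  size_t osp = (size_t)ox * oy * oz, isp = (size_t)nx * ny * nz;
  NumericVector gx((R_xlen_t)(isp * ci)), gw(w.size()), gb(co);
  double *GX = REAL(gx), *GW = REAL(gw), *GB = REAL(gb);
  double *X = REAL(x), *W = REAL(w), *GO = REAL(gout);
  for (int c = 0; c < co; ++c) {
    double *Gc = GO + osp * c, s = 0.0;
    for (size_t i = 0; i < osp; ++i) s += Gc[i];
    GB[c] = s;
  }
  for (int c = 0; c < co; ++c) {
    double *Gc = GO + osp * c;
    for (int ic = 0; ic < ci; ++ic) {
      double *Xc = X + isp * ic, *GXc = GX + isp * ic;
      for (int kz = 0; kz < 2; ++kz)
      for (int ky = 0; ky < 2; ++ky)
      for (int kx = 0; kx < 2; ++kx) {
        size_t wi = kx + 2 * (ky + 2 * (kz + 2 * (ic + (size_t)ci * c)));
        double wv = W[wi], acc = 0.0;
        for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
          double *Grow = Gc + (size_t)ox * ((2 * y + ky) + (size_t)oy * (2 * z + kz));
          double *Xrow = Xc + (size_t)nx * (y + (size_t)ny * z);
          double *GXrow = GXc + (size_t)nx * (y + (size_t)ny * z);
          for (int xv = 0; xv < nx; ++xv) {
            double g = Grow[2 * xv + kx];
            acc += g * Xrow[xv];
            GXrow[xv] += g * wv;
          }
        }
        GW[wi] = acc;
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, ci);
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---- trilinear warp (backward-warping spatial transformer) -----------------
// ddf is in voxel units on the output grid; border (clamp) extension.
// mode 0 = trilinear, 1 = nearest neighbour.

// [[Rcpp::export]]
NumericVector cp_warp_fw(NumericVector moving, IntegerVector md,
                         NumericVector ddf, int mode) {
  int nx = md[0], ny = md[1], nz = md[2];
  size_t nsp = (size_t)nx * ny * nz;
  NumericVector out((R_xlen_t)nsp);
  double *O = REAL(out), *M = REAL(moving), *U = REAL(ddf);
  double *Ux = U, *Uy = U + nsp, *Uz = U + 2 * nsp;
  size_t i = 0;
  for (int z = 0; z < nz; ++z)
  for (int y = 0; y < ny; ++y)
  for (int x = 0; x < nx; ++x, ++i) {
    double px = x + Ux[i], py = y + Uy[i], pz = z + Uz[i];
    if (px < 0) px = 0; if (px > nx - 1) px = nx - 1;
    if (py < 0) py = 0; if (py > ny - 1) py = ny - 1;
    if (pz < 0) pz = 0; if (pz > nz - 1) pz = nz - 1;
    if (mode == 1) {
      int ix = (int)std::floor(px + 0.5), iy = (int)std::floor(py + 0.5),
          iz = (int)std::floor(pz + 0.5);
      O[i] = M[IDX3(ix, iy, iz, nx, ny)];
    } else {
      int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
      if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
      if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
      if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
      double tx = px - x0, ty = py - y0, tz = pz - z0;
      double c000 = M[IDX3(x0, y0, z0, nx, ny)],     c100 = M[IDX3(x0 + 1, y0, z0, nx, ny)];
      double c010 = M[IDX3(x0, y0 + 1, z0, nx, ny)], c110 = M[IDX3(x0 + 1, y0 + 1, z0, nx, ny)];
      double c001 = M[IDX3(x0, y0, z0 + 1, nx, ny)], c101 = M[IDX3(x0 + 1, y0, z0 + 1, nx, ny)];
      double c011 = M[IDX3(x0, y0 + 1, z0 + 1, nx, ny)], c111 = M[IDX3(x0 + 1, y0 + 1, z0 + 1, nx, ny)];
      double c00 = c000 + tx * (c100 - c000), c10 = c010 + tx * (c110 - c010);
      double c01 = c001 + tx * (c101 - c001), c11 = c011 + tx * (c111 - c011);
      double c0 = c00 + ty * (c10 - c00), c1 = c01 + ty * (c11 - c01);
      O[i] = c0 + tz * (c1 - c0);
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Gradient of the trilinear warp with respect to the (voxel-unit) ddf.
// Samples clamped at the border get zero coordinate gradient.

// [[Rcpp::export]]
NumericVector cp_warp_bw_ddf(NumericVector moving, IntegerVector md,
                             NumericVector ddf, NumericVector gout) {
  int nx = md[0], ny = md[1], nz = md[2];
  size_t nsp = (size_t)nx * ny * nz;
  NumericVector gddf((R_xlen_t)(3 * nsp));
  double *G = REAL(gddf), *M = REAL(moving), *U = REAL(ddf), *GO = REAL(gout);
  double *Ux = U, *Uy = U + nsp, *Uz = U + 2 * nsp;
  double *Gx = G, *Gy = G + nsp, *Gz = G + 2 * nsp;
  size_t i = 0;
  for (int z = 0; z < nz; ++z)
  for (int y = 0; y < ny; ++y)
  for (int x = 0; x < nx; ++x, ++i) {
    double px = x + Ux[i], py = y + Uy[i], pz = z + Uz[i];
    bool cx = (px < 0 || px > nx - 1), cy = (py < 0 || py > ny - 1),
         cz = (pz < 0 || pz > nz - 1);
    if (px < 0) px = 0; if (px > nx - 1) px = nx - 1;
    if (py < 0) py = 0; if (py > ny - 1) py = ny - 1;
    if (pz < 0) pz = 0; if (pz > nz - 1) pz = nz - 1;
    int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
    if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
    if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
    if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
    double tx = px - x0, ty = py - y0, tz = pz - z0;
    double c000 = M[IDX3(x0, y0, z0, nx, ny)],     c100 = M[IDX3(x0 + 1, y0, z0, nx, ny)];
    double c010 = M[IDX3(x0, y0 + 1, z0, nx, ny)], c110 = M[IDX3(x0 + 1, y0 + 1, z0, nx, ny)];
    double c001 = M[IDX3(x0, y0, z0 + 1, nx, ny)], c101 = M[IDX3(x0 + 1, y0, z0 + 1, nx, ny)];
    double c011 = M[IDX3(x0, y0 + 1, z0 + 1, nx, ny)], c111 = M[IDX3(x0 + 1, y0 + 1, z0 + 1, nx, ny)];
    double g = GO[i];
    double dx = (1 - ty) * (1 - tz) * (c100 - c000) + ty * (1 - tz) * (c110 - c010) +
                (1 - ty) * tz * (c101 - c001) + ty * tz * (c111 - c011);
    double dy = (1 - tx) * (1 - tz) * (c010 - c000) + tx * (1 - tz) * (c110 - c100) +
                (1 - tx) * tz * (c011 - c001) + tx * tz * (c111 - c101);
    double dz = (1 - tx) * (1 - ty) * (c001 - c000) + tx * (1 - ty) * (c101 - c100) +
                (1 - tx) * ty * (c011 - c010) + tx * ty * (c111 - c110);
    Gx[i] = cx ? 0.0 : g * dx;
    Gy[i] = cy ? 0.0 : g * dy;
    Gz[i] = cz ? 0.0 : g * dz;
  }
  gddf.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return gddf;
}

// ---- exact Euclidean distance transform (Felzenszwalb-Huttenlocher) --------
// Squared distance (mm^2) to the nearest foreground voxel centre,
// anisotropic spacing supported.

static void dt1d(std::vector<double> &f, std::vector<double> &d, int n, double h) {
  std::vector<int> v(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  v[0] = 0; zz[0] = -1e30; zz[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = ((f[q] + q * h * q * h) - (f[p] + p * h * p * h)) / (2.0 * h * (q - p));
      if (s <= zz[k]) { --k; } else break;
    }
    ++k; v[k] = q; zz[k] = s; zz[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[k + 1] < q * h) ++k;
    double dx = (q - v[k]) * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cp_edt_sq(NumericVector mask, IntegerVector md, NumericVector spacing) {
  int nx = md[0], ny = md[1], nz = md[2];
  size_t nsp = (size_t)nx * ny * nz;
  NumericVector out((R_xlen_t)nsp);
  double *O = REAL(out), *Mk = REAL(mask);
  for (size_t i = 0; i < nsp; ++i) O[i] = (Mk[i] > 0.5) ? 0.0 : 1e20;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  // x pass
  for (int z = 0; z < nz; ++z)
  for (int y = 0; y < ny; ++y) {
    double *row = O + IDX3(0, y, z, nx, ny);
    for (int x = 0; x < nx; ++x) f[x] = row[x];
    dt1d(f, d, nx, spacing[0]);
    for (int x = 0; x < nx; ++x) row[x] = d[x];
  }
  // y pass
  for (int z = 0; z < nz; ++z)
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) f[y] = O[IDX3(x, y, z, nx, ny)];
    dt1d(f, d, ny, spacing[1]);
    for (int y = 0; y < ny; ++y) O[IDX3(x, y, z, nx, ny)] = d[y];
  }
  // z pass
  for (int y = 0; y < ny; ++y)
  for (int x = 0; x < nx; ++x) {
    for (int z = 0; z < nz; ++z) f[z] = O[IDX3(x, y, z, nx, ny)];
    dt1d(f, d, nz, spacing[2]);
    for (int z = 0; z < nz; ++z) O[IDX3(x, y, z, nx, ny)] = d[z];
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// ---- trilinear / nearest resize between grids ------------------------------
// Samples the input at positions mapping output voxel centres onto the input
// index range (align-corners convention). mode 0 linear, 1 nearest.

// [[Rcpp::export]]
NumericVector cp_resize3d(NumericVector vol, IntegerVector vd, IntegerVector od, int mode) {
  int nx = vd[0], ny = vd[1], nz = vd[2];
  int ox = od[0], oy = od[1], oz = od[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  double *O = REAL(out), *V = REAL(vol);
  double sx = ox > 1 ? (double)(nx - 1) / (ox - 1) : 0.0;
  double sy = oy > 1 ? (double)(ny - 1) / (oy - 1) : 0.0;
  double sz = oz > 1 ? (double)(nz - 1) / (oz - 1) : 0.0;
  size_t i = 0;
  for (int z = 0; z < oz; ++z)
  for (int y = 0; y < oy; ++y)
  for (int x = 0; x < ox; ++x, ++i) {
    double px = x * sx, py = y * sy, pz = z * sz;
    if (mode == 1) {
      O[i] = V[IDX3((int)std::floor(px + 0.5), (int)std::floor(py + 0.5),
                    (int)std::floor(pz + 0.5), nx, ny)];
    } else {
      int x0 = std::min((int)std::floor(px), nx - 2); if (x0 < 0) x0 = 0;
      int y0 = std::min((int)std::floor(py), ny - 2); if (y0 < 0) y0 = 0;
      int z0 = std::min((int)std::floor(pz), nz - 2); if (z0 < 0) z0 = 0;
      double tx = px - x0, ty = py - y0, tz = pz - z0;
      double c00 = V[IDX3(x0, y0, z0, nx, ny)] * (1 - tx) + V[IDX3(x0 + 1, y0, z0, nx, ny)] * tx;
      double c10 = V[IDX3(x0, y0 + 1, z0, nx, ny)] * (1 - tx) + V[IDX3(x0 + 1, y0 + 1, z0, nx, ny)] * tx;
      double c01 = V[IDX3(x0, y0, z0 + 1, nx, ny)] * (1 - tx) + V[IDX3(x0 + 1, y0, z0 + 1, nx, ny)] * tx;
      double c11 = V[IDX3(x0, y0 + 1, z0 + 1, nx, ny)] * (1 - tx) + V[IDX3(x0 + 1, y0 + 1, z0 + 1, nx, ny)] * tx;
      double c0 = c00 * (1 - ty) + c10 * ty, c1 = c01 * (1 - ty) + c11 * ty;
      O[i] = c0 * (1 - tz) + c1 * tz;
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}
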