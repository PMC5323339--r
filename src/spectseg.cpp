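#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a 3-D lattice at world points.
// Points outside the voxel-centre hull return 0 (count images decay to 0).
static double trilinear_one(const double *vals, int nx, int ny, int nz,
                            const double *sp, const double *orig,
                            double px, double py, double pz) {
  double fx = (px - orig[0]) / sp[0];
  double fy = (py - orig[1]) / sp[1];
  double fz = (pz - orig[2]) / sp[2];
  if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 || fz > nz - 1)
    return 0.0;
  int ix = (int)std::floor(fx); if (ix > nx - 2) ix = nx - 2; if (nx == 1) ix = 0;
  int iy = (int)std::floor(fy); if (iy > ny - 2) iy = ny - 2; if (ny == 1) iy = 0;
  int iz = (int)std::floor(fz); if (iz > nz - 2) iz = nz - 2; if (nz == 1) iz = 0;
  double tx = fx - ix, ty = fy - iy, tz = fz - iz;
  if (nx == 1) tx = 0; if (ny == 1) ty = 0; if (nz == 1) tz = 0;
  int ix1 = (nx == 1) ? ix : ix + 1;
  int iy1 = (ny == 1) ? iy : iy + 1;
  int iz1 = (nz == 1) ? iz : iz + 1;
  size_t sxy = (size_t)nx * ny;
#define V(i, j, k) vals[(i) + (size_t)nx * (j) + sxy * (k)]
  double c00 = V(ix, iy, iz)  * (1 - tx) + V(ix1, iy, iz)  * tx;
  double c10 = V(ix, iy1, iz) * (1 - tx) + V(ix1, iy1, iz) * tx;
  double c01 = V(ix, iy, iz1) * (1 - tx) + V(ix1, iy, iz1) * tx;
  double c11 = V(ix, iy1, iz1) * (1 - tx) + V(ix1, iy1, iz1) * tx;
#undef V
  double c0 = c00 * (1 - ty) + c10 * ty;
  double c1 = c01 * (1 - ty) + c11 * ty;
  return c0 * (1 - tz) + c1 * tz;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector values, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix pts) {
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = trilinear_one(values.begin(), dim[0], dim[1], dim[2],
                           spacing.begin(), origin.begin(),
                           pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// 6-connected flood fill from the grid border over non-member voxels:
// returns the "background" labelling used by solidify().
// [[Rcpp::export]]
LogicalVector cpp_flood_background(LogicalVector member, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> bg(n, 0);
  std::queue<size_t> q;
  size_t sxy = (size_t)nx * ny;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1) {
          size_t idx = i + (size_t)nx * j + sxy * k;
          if (!member[idx] && !bg[idx]) { bg[idx] = 1; q.push(idx); }
        }
      }
  while (!q.empty()) {
    size_t idx = q.front(); q.pop();
    int k = (int)(idx / sxy);
    int rem = (int)(idx % sxy);
    int j = rem / nx, i = rem % nx;
    for (int d = 0; d < 6; ++d) {
      int ii = i + (d == 1) - (d == 0);
      int jj = j + (d == 3) - (d == 2);
      int kk = k + (d == 5) - (d == 4);
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      size_t nb = ii + (size_t)nx * jj + sxy * kk;
      if (!member[nb] && !bg[nb]) { bg[nb] = 1; q.push(nb); }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = bg[i] != 0;
  return out;
}

// 6-connected component of `candidate` containing linear index `seed` (0-based).
// [[Rcpp::export]]
LogicalVector cpp_component_from_seed(LogicalVector candidate, IntegerVector dim,
                                      int seed) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  size_t sxy = (size_t)nx * ny;
  LogicalVector out(n);
  if (seed < 0 || (size_t)seed >= n || !candidate[seed]) return out;
  std::vector<char> seen(n, 0);
  std::queue<size_t> q;
  seen[seed] = 1; q.push((size_t)seed);
  while (!q.empty()) {
    size_t idx = q.front(); q.pop();
    out[idx] = true;
    int k = (int)(idx / sxy);
    int rem = (int)(idx % sxy);
    int j = rem / nx, i = rem % nx;
    for (int d = 0; d < 6; ++d) {
      int ii = i + (d == 1) - (d == 0);
      int jj = j + (d == 3) - (d == 2);
      int kk = k + (d == 5) - (d == 4);
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      size_t nb = ii + (size_t)nx * jj + sxy * kk;
      if (candidate[nb] && !seen[nb]) { seen[nb] = 1; q.push(nb); }
    }
  }
  return out;
}

// 6-connected component labelling (first-come ordering); labels start at 1,
// 0 = not a member.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector member, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  size_t sxy = (size_t)nx * ny;
  IntegerVector lab(n);
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < n; ++s) {
    if (!member[s] || lab[s]) continue;
    lab[s] = ++next; q.push(s);
    while (!q.empty()) {
      size_t idx = q.front(); q.pop();
      int k = (int)(idx / sxy);
      int rem = (int)(idx % sxy);
      int j = rem / nx, i = rem % nx;
      for (int d = 0; d < 6; ++d) {
        int ii = i + (d == 1) - (d == 0);
        int jj = j + (d == 3) - (d == 2);
        int kk = k + (d == 5) - (d == 4);
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        size_t nb = ii + (size_t)nx * jj + sxy * kk;
        if (member[nb] && !lab[nb]) { lab[nb] = next; q.push(nb); }
      }
    }
  }
  return lab;
}

// Edge-strength objective for a Fourier surface (downhill-simplex hot loop).
// Bt_val/Bt_du/Bt_dv: TRANSPOSED basis matrices (ncoef x nodes), so one
// node's basis values are contiguous; coef: ncoef x 3.
// gx/gy/gz: gradient component lattices. polarity: +1 hot object (keep
// contributions with grad.n_out < 0), -1 cold, 0 = keep all (delta == 1).
// Returns c(numerator, total_area).
// [[Rcpp::export]]
NumericVector cpp_objective_parts(NumericMatrix Bt_val, NumericMatrix Bt_du,
                                  NumericMatrix Bt_dv, NumericMatrix coef,
                                  NumericVector gx, NumericVector gy,
                                  NumericVector gz, IntegerVector dim,
                                  NumericVector spacing, NumericVector origin,
                                  int polarity) {
  int p = Bt_val.nrow(), n = Bt_val.ncol();
  double cx = coef(0, 0), cy = coef(0, 1), cz = coef(0, 2);
  const double *BV = Bt_val.begin(), *BU = Bt_du.begin(), *BW = Bt_dv.begin();
  const double *C0 = &coef(0, 0), *C1 = &coef(0, 1), *C2 = &coef(0, 2);
  double num = 0.0, area = 0.0;
  for (int i = 0; i < n; ++i) {
    double px = 0, py = 0, pz = 0, dux = 0, duy = 0, duz = 0,
           dvx = 0, dvy = 0, dvz = 0;
    const double *bv = BV + (size_t)p * i;
    const double *bu = BU + (size_t)p * i;
    const double *bw = BW + (size_t)p * i;
    for (int j = 0; j < p; ++j) {
      double c0 = C0[j], c1 = C1[j], c2 = C2[j];
      px += bv[j] * c0; py += bv[j] * c1; pz += bv[j] * c2;
      dux += bu[j] * c0; duy += bu[j] * c1; duz += bu[j] * c2;
      dvx += bw[j] * c0; dvy += bw[j] * c1; dvz += bw[j] * c2;
    }
    // normal = d/du x d/dv, flipped to point away from the centre coefficient
    // (the raw, unflipped normal is kept in delta == 1 mode, where the sum is
    // a discrete closed-surface flux)
    double nxv = duy * dvz - duz * dvy;
    double nyv = duz * dvx - dux * dvz;
    double nzv = dux * dvy - duy * dvx;
    if (polarity != 0) {
      double outd = nxv * (px - cx) + nyv * (py - cy) + nzv * (pz - cz);
      if (outd < 0) { nxv = -nxv; nyv = -nyv; nzv = -nzv; }
    }
    area += std::sqrt(nxv * nxv + nyv * nyv + nzv * nzv);
    double gvx = trilinear_one(gx.begin(), dim[0], dim[1], dim[2],
                               spacing.begin(), origin.begin(), px, py, pz);
    double gvy = trilinear_one(gy.begin(), dim[0], dim[1], dim[2],
                               spacing.begin(), origin.begin(), px, py, pz);
    double gvz = trilinear_one(gz.begin(), dim[0], dim[1], dim[2],
                               spacing.begin(), origin.begin(), px, py, pz);
    double gn = gvx * nxv + gvy * nyv + gvz * nzv;
    if (polarity > 0) {           // hot object: gradient points inward at edge
      if (gn < 0) num += -gn;
    } else if (polarity < 0) {    // cold object
      if (gn > 0) num += gn;
    } else {
      num += gn;                  // delta forced to 1 (diagnostics/tests)
    }
  }
  return NumericVector::create(num, area);
}

// Inside/outside classification of voxel centres against a densely sampled
// surface: nearest surface sample via a coarse-to-fine search on the (u,v)
// sample grid, then sign of (voxel - point) . outward normal.
// pts/nrm are fine-grid samples in column-major (iu fastest) order of an
// nu x nv lattice; u wraps, v does not. `factor` = coarse decimation.
// [[Rcpp::export]]
LogicalVector cpp_classify_inside(NumericMatrix vox, NumericMatrix pts,
                                  NumericMatrix nrm, int nu, int nv,
                                  int factor) {
  int nvox = vox.nrow();
  LogicalVector out(nvox);
  int cu = nu / factor, cv = nv / factor;
  std::vector<int> coarse_idx;
  coarse_idx.reserve((size_t)cu * cv);
  for (int j = 0; j < cv; ++j)
    for (int i = 0; i < cu; ++i)
      coarse_idx.push_back(i * factor + nu * (j * factor));
  int win = factor + factor / 2 + 1;  // fine-window half-width around coarse hit
  for (int vI = 0; vI < nvox; ++vI) {
    double vx = vox(vI, 0), vy = vox(vI, 1), vz = vox(vI, 2);
    double best = R_PosInf; int bi = 0;
    for (size_t c = 0; c < coarse_idx.size(); ++c) {
      int s = coarse_idx[c];
      double dx = vx - pts(s, 0), dy = vy - pts(s, 1), dz = vz - pts(s, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bi = s; }
    }
    int biu = bi % nu, biv = bi / nu;
    best = R_PosInf; int fi = bi;
    for (int dj = -win; dj <= win; ++dj) {
      int jv = biv + dj;
      if (jv < 0 || jv >= nv) continue;
      for (int di = -win; di <= win; ++di) {
        int iu = ((biu + di) % nu + nu) % nu;  // u wraps
        int s = iu + nu * jv;
        double dx = vx - pts(s, 0), dy = vy - pts(s, 1), dz = vz - pts(s, 2);
        double d = dx * dx + dy * dy + dz * dz;
        if (d < best) { best = d; fi = s; }
      }
    }
    double dot = (vx - pts(fi, 0)) * nrm(fi, 0) +
                 (vy - pts(fi, 1)) * nrm(fi, 1) +
                 (vz - pts(fi, 2)) * nrm(fi, 2);
    out[vI] = dot < 0;
  }
  return out;
}
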