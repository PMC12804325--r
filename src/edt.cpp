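#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// 1-D squared distance transform of a sampled function (Felzenszwalb &
// Huttenlocher 2012) on a line of n samples with physical spacing w.
// Reads f, writes d. All values finite.
static void dt1d(const double* f, double* d, int n, double w,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double xq = q * w, s;
    for (;;) {
      double xp = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k] && k > 0) { k--; } else break;
    }
    if (s <= z[k] && k == 0) { v[0] = q; continue; } // replaces the only parabola
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * w;
    while (z[k + 1] < xq) k++;
    double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel centre to the nearest
// TRUE voxel centre of `target`, honouring anisotropic spacing. If `target`
// has no TRUE voxel the result is a large finite sentinel everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector target, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // finite stand-in for "no target on this line yet"; larger than any
  // achievable squared distance within the grid
  double ex = nx * sx, ey = ny * sy, ez = nz * sz;
  const double BIG = 4.0 * (ex * ex + ey * ey + ez * ez) + 1.0;

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = target[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x passes (unit stride)
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      double* col = &out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx];
      dt1d(col, d.data(), nx, sx, v, z);
      std::copy(d.begin(), d.begin() + nx, col);
    }
  // y passes
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      for (int j = 0; j < ny; j++)
        f[j] = out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i];
      dt1d(f.data(), d.data(), ny, sy, v, z);
      for (int j = 0; j < ny; j++)
        out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = d[j];
    }
  // z passes
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      for (int k = 0; k < nz; k++)
        f[k] = out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i];
      dt1d(f.data(), d.data(), nz, sz, v, z);
      for (int k = 0; k < nz; k++)
        out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = d[k];
    }
  // cap distances influenced by the sentinel (no-target case)
  for (R_xlen_t i = 0; i < n; i++)
    if (out[i] > BIG) out[i] = BIG;
  return out;
}

// Rasterize a union of axis-aligned ellipsoids: a voxel is foreground iff
// its centre lies inside (or on) any solid. Centres are physical mm
// relative to the grid centre; voxel centre i (0-based) sits at
// (i - (n-1)/2) * spacing. `semiaxes` holds one row (a, b, c) per solid;
// a sphere has a = b = c = radius. Solids with any semiaxis <= 0 are
// skipped (clamped-away solids rasterize to nothing).
// [[Rcpp::export]]
LogicalVector cpp_rasterize_solids(IntegerVector dim, NumericVector spacing,
                                   NumericMatrix centers,
                                   NumericMatrix semiaxes) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double cx0 = (nx - 1) / 2.0, cy0 = (ny - 1) / 2.0,
               cz0 = (nz - 1) / 2.0;
  LogicalVector out((R_xlen_t)nx * ny * nz); // initialised FALSE
  for (int s = 0; s < centers.nrow(); s++) {
    double ra = semiaxes(s, 0), rb = semiaxes(s, 1), rc = semiaxes(s, 2);
    if (ra <= 0 || rb <= 0 || rc <= 0) continue;
    double cx = centers(s, 0), cy = centers(s, 1), cz = centers(s, 2);
    int i0 = std::max(0, (int)std::ceil((cx - ra) / sx + cx0));
    int i1 = std::min(nx - 1, (int)std::floor((cx + ra) / sx + cx0));
    int j0 = std::max(0, (int)std::ceil((cy - rb) / sy + cy0));
    int j1 = std::min(ny - 1, (int)std::floor((cy + rb) / sy + cy0));
    int k0 = std::max(0, (int)std::ceil((cz - rc) / sz + cz0));
    int k1 = std::min(nz - 1, (int)std::floor((cz + rc) / sz + cz0));
    for (int k = k0; k <= k1; k++) {
      double dz = ((k - cz0) * sz - cz) / rc, dz2 = dz * dz;
      for (int j = j0; j <= j1; j++) {
        double dy = ((j - cy0) * sy - cy) / rb, dyz2 = dy * dy + dz2;
        if (dyz2 > 1.0) continue;
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = i0; i <= i1; i++) {
          double dx = ((i - cx0) * sx - cx) / ra;
          if (dx * dx + dyz2 <= 1.0) out[base + i] = TRUE;
        }
      }
    }
  }
  return out;
}

// Foreground voxels with at least one 6-connected background neighbour
// (voxels on the grid border count as touching background).
// [[Rcpp::export]]
LogicalVector cpp_surface(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t idx = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
        if (!mask[idx]) continue;
        bool surf =
            i == 0 || i == nx - 1 || j == 0 || j == ny - 1 || k == 0 ||
            k == nz - 1 || !mask[idx - 1] || !mask[idx + 1] ||
            !mask[idx - nx] || !mask[idx + nx] ||
            !mask[idx - (R_xlen_t)nx * ny] || !mask[idx + (R_xlen_t)nx * ny];
        if (surf) out[idx] = TRUE;
      }
  return out;
}

// forward declaration (defined above)
// dt1d is file-local; reuse cpp_edt_sq machinery via a small helper that
// runs the 3-pass transform in place on a raw buffer.
static void edt3_inplace(std::vector<double>& g, int nx, int ny, int nz,
                         double sx, double sy, double sz) {
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      double* col = &g[(size_t)k * nx * ny + (size_t)j * nx];
      dt1d(col, d.data(), nx, sx, v, z);
      std::copy(d.begin(), d.begin() + nx, col);
    }
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      for (int j = 0; j < ny; j++)
        f[j] = g[(size_t)k * nx * ny + (size_t)j * nx + i];
      dt1d(f.data(), d.data(), ny, sy, v, z);
      for (int j = 0; j < ny; j++)
        g[(size_t)k * nx * ny + (size_t)j * nx + i] = d[j];
    }
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      for (int k = 0; k < nz; k++)
        f[k] = g[(size_t)k * nx * ny + (size_t)j * nx + i];
      dt1d(f.data(), d.data(), nz, sz, v, z);
      for (int k = 0; k < nz; k++)
        g[(size_t)k * nx * ny + (size_t)j * nx + i] = d[k];
    }
}

// Displace a mask boundary by `offset` mm (positive = dilate, negative =
// erode) via the signed-distance threshold, using a single distance
// transform. The mask boundary is taken to lie half a voxel beyond the
// outermost foreground voxel centres (half-voxel correction), so that
// sub-voxel offsets act symmetrically instead of being swallowed by the
// centre-to-centre distance quantum: dilation keeps background voxels
// with d_fg <= offset + h, erosion keeps foreground voxels with
// d_bg >= |offset| + h. h = a quarter of the smallest spacing centres
// the realized boundary displacement on the requested offset (verified
// against analytic sphere volumes).
// [[Rcpp::export]]
LogicalVector cpp_offset_mask(LogicalVector mask, IntegerVector dim,
                              NumericVector spacing, double offset) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const size_t n = (size_t)nx * ny * nz;
  double ex = nx * sx, ey = ny * sy, ez = nz * sz;
  const double BIG = 4.0 * (ex * ex + ey * ey + ez * ez) + 1.0;
  const double h = 0.25 * std::min(sx, std::min(sy, sz));
  LogicalVector out(n);
  std::vector<double> g(n);
  if (offset >= 0) { // distance to foreground
    for (size_t i = 0; i < n; i++) g[i] = mask[i] ? 0.0 : BIG;
    edt3_inplace(g, nx, ny, nz, sx, sy, sz);
    double t = offset + h, o2 = t * t;
    for (size_t i = 0; i < n; i++) out[i] = mask[i] || g[i] <= o2;
  } else { // distance to background
    for (size_t i = 0; i < n; i++) g[i] = mask[i] ? BIG : 0.0;
    edt3_inplace(g, nx, ny, nz, sx, sy, sz);
    double t = -offset + h, o2 = t * t;
    for (size_t i = 0; i < n; i++) out[i] = mask[i] && g[i] >= o2;
  }
  return out;
}

// Minimum ablative margin core: minimum over tumor surface voxels of the
// signed distance to the ablation boundary, with one distance transform.
// If every tumor surface voxel lies inside the ablation, the minimum is
// the smallest distance to non-ablation tissue (positive); otherwise it
// is minus the largest distance from an uncovered tumor voxel to the
// ablation (negative). Returns [mam, n_uncovered].
// [[Rcpp::export]]
NumericVector cpp_mam(LogicalVector tumor, LogicalVector ablation,
                      IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const size_t n = (size_t)nx * ny * nz;
  double ex = nx * sx, ey = ny * sy, ez = nz * sz;
  const double BIG = 4.0 * (ex * ex + ey * ey + ez * ez) + 1.0;

  // tumor surface (6-connectivity; grid border counts as background)
  std::vector<char> surf(n, 0);
  size_t n_unc = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        size_t idx = (size_t)k * nx * ny + (size_t)j * nx + i;
        if (!tumor[idx]) continue;
        if (!ablation[idx]) n_unc++;
        bool s = i == 0 || i == nx - 1 || j == 0 || j == ny - 1 ||
                 k == 0 || k == nz - 1 || !tumor[idx - 1] ||
                 !tumor[idx + 1] || !tumor[idx - nx] || !tumor[idx + nx] ||
                 !tumor[idx - (size_t)nx * ny] ||
                 !tumor[idx + (size_t)nx * ny];
        if (s) surf[idx] = 1;
      }

  std::vector<double> g(n);
  double mam;
  if (n_unc == 0) { // covered: distance to nearest background-of-ablation
    for (size_t i = 0; i < n; i++) g[i] = ablation[i] ? BIG : 0.0;
    edt3_inplace(g, nx, ny, nz, sx, sy, sz);
    double m2 = BIG;
    for (size_t i = 0; i < n; i++)
      if (surf[i] && g[i] < m2) m2 = g[i];
    mam = std::sqrt(m2);
  } else { // uncovered: minus the largest distance to the ablation
    for (size_t i = 0; i < n; i++) g[i] = ablation[i] ? 0.0 : BIG;
    edt3_inplace(g, nx, ny, nz, sx, sy, sz);
    double m2 = 0.0;
    for (size_t i = 0; i < n; i++)
      if (tumor[i] && !ablation[i] && g[i] > m2) m2 = g[i];
    mam = -std::sqrt(m2);
  }
  return NumericVector::create(mam, (double)n_unc);
}

// 1-based inclusive bounding box of TRUE voxels: returns
// (lo1, lo2, lo3, hi1, hi2, hi3), or all zeros when the mask is empty.
// [[Rcpp::export]]
IntegerVector cpp_bbox(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int lo[3] = {nx, ny, nz}, hi[3] = {-1, -1, -1};
  size_t idx = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, idx++) {
        if (!mask[idx]) continue;
        if (i < lo[0]) lo[0] = i;
        if (j < lo[1]) lo[1] = j;
        if (k < lo[2]) lo[2] = k;
        if (i > hi[0]) hi[0] = i;
        if (j > hi[1]) hi[1] = j;
        if (k > hi[2]) hi[2] = k;
      }
  if (hi[0] < 0) return IntegerVector::create(0, 0, 0, 0, 0, 0);
  return IntegerVector::create(lo[0] + 1, lo[1] + 1, lo[2] + 1,
                               hi[0] + 1, hi[1] + 1, hi[2] + 1);
}
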