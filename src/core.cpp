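#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Parallel-beam forward projection with an exact pixel footprint
// (distance-driven): the projection of a unit square pixel at angle
// theta is a trapezoid (convolution of two boxes of widths |cos| and
// |sin|), which is integrated analytically over each detector bin.
// Path lengths are returned in pixel units (multiply by spacing for
// physical lengths).  Detector bin pitch equals the pixel size.

// trapezoid CDF: mass fraction of the footprint left of x (x relative
// to the footprint center), for box widths A >= B
static inline double trap_cdf(double x, double a, double b) {
  double w = (a + b) / 2.0, d = (a - b) / 2.0;
  if (x <= -w) return 0.0;
  if (x >= w) return 1.0;
  if (b < 1e-9) return (x + w) / a;
  if (x < -d) return (x + w) * (x + w) / (2.0 * a * b);
  if (x <= d) return b / (2.0 * a) + (x + d) / a;
  return 1.0 - (w - x) * (w - x) / (2.0 * a * b);
}

// labels: nx*ny integer slice (1-based material labels, 0 = none)
// returns: nbins x nangles x nmat array of path lengths
// [[Rcpp::export]]
NumericVector cpp_project_paths(IntegerVector labels, int nx, int ny,
                                int nmat, NumericVector angles, int nbins) {
  int na = angles.size();
  NumericVector out(Dimension(nbins, na, nmat));
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double t0 = (nbins - 1) / 2.0;
  for (int a = 0; a < na; ++a) {
    double ca = cos(angles[a]), sa = sin(angles[a]);
    double A = std::max(std::fabs(ca), std::fabs(sa));
    double B = std::min(std::fabs(ca), std::fabs(sa));
    double w = (A + B) / 2.0;
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int lab = labels[i + nx * j];
        if (lab <= 0) continue;
        double u = (i - cx) * ca + (j - cy) * sa + t0;
        int blo = (int)std::floor(u - w + 0.5);
        int bhi = (int)std::floor(u + w + 0.5);
        double *o = &out[nbins * (a + na * (size_t)(lab - 1))];
        double prev = trap_cdf(blo - 0.5 - u, A, B);
        for (int b = blo; b <= bhi; ++b) {
          double cur = trap_cdf(b + 0.5 - u, A, B);
          if (b >= 0 && b < nbins) o[b] += cur - prev;
          prev = cur;
        }
      }
    }
  }
  return out;
}

// Same geometry for fractional per-material occupancy volumes
// (partial-volume phantoms).  fracs: nx*ny*nmat.
// [[Rcpp::export]]
NumericVector cpp_project_fracs(NumericVector fracs, int nx, int ny,
                                int nmat, NumericVector angles, int nbins) {
  int na = angles.size();
  NumericVector out(Dimension(nbins, na, nmat));
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double t0 = (nbins - 1) / 2.0;
  for (int a = 0; a < na; ++a) {
    double ca = cos(angles[a]), sa = sin(angles[a]);
    double A = std::max(std::fabs(ca), std::fabs(sa));
    double B = std::min(std::fabs(ca), std::fabs(sa));
    double w = (A + B) / 2.0;
    for (int m = 0; m < nmat; ++m) {
      double *o = &out[nbins * (a + na * (size_t)m)];
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          double v = fracs[i + nx * (j + (size_t)ny * m)];
          if (v <= 0) continue;
          double u = (i - cx) * ca + (j - cy) * sa + t0;
          int blo = (int)std::floor(u - w + 0.5);
          int bhi = (int)std::floor(u + w + 0.5);
          double prev = trap_cdf(blo - 0.5 - u, A, B);
          for (int b = blo; b <= bhi; ++b) {
            double cur = trap_cdf(b + 0.5 - u, A, B);
            if (b >= 0 && b < nbins) o[b] += v * (cur - prev);
            prev = cur;
          }
        }
      }
    }
  }
  return out;
}

// Backprojection of filtered projections onto an nx x ny slice.
// proj: nbins x nangles filtered sinogram slice.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector proj, int nbins,
                              NumericVector angles, int nx, int ny) {
  int na = angles.size();
  NumericVector img(nx * ny);
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double s0 = (nbins - 1) / 2.0;
  for (int a = 0; a < na; ++a) {
    double ca = cos(angles[a]), sa = sin(angles[a]);
    const double *p = &proj[nbins * (size_t)a];
    for (int j = 0; j < ny; ++j) {
      double sy = (j - cy) * sa + s0;
      for (int i = 0; i < nx; ++i) {
        double s = (i - cx) * ca + sy;
        int b = (int)std::floor(s);
        if (b < 0 || b + 1 >= nbins) continue;
        double f = s - b;
        img[i + nx * j] += p[b] * (1.0 - f) + p[b + 1] * f;
      }
    }
  }
  double w = M_PI / (2.0 * na);          // FBP angular weighting
  for (int k = 0; k < nx * ny; ++k) img[k] *= w;
  return img;
}

// Seeded region growing with local dynamic tolerance.  A frontier voxel
// joins when |g - m_loc| <= k * s_loc where m_loc, s_loc are the mean and
// std of already-accepted voxels within a cube of radius r around the
// candidate.  Before any local std is established (fewer than 8 accepted
// neighbours, or s_loc == 0) the global std of the seed neighbourhood
// `s_init` is used.  Deterministic: FIFO queue, neighbours pushed in
// fixed index order (26-connectivity).
// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dim,
                              IntegerMatrix seeds, double k, int r,
                              double s_init) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  LogicalVector acc(n);
  std::vector<char> queued(n, 0);
  std::queue<size_t> q;
  for (int i = 0; i < seeds.nrow(); ++i) {
    size_t idx = (seeds(i, 0) - 1) +
      (size_t)nx * ((seeds(i, 1) - 1) + (size_t)ny * (seeds(i, 2) - 1));
    if (!acc[idx]) { acc[idx] = true; }
  }
  // push neighbours of seeds
  std::vector<size_t> init;
  for (size_t idx = 0; idx < n; ++idx) if (acc[idx]) init.push_back(idx);
  auto push_nb = [&](size_t idx) {
    int z = idx / ((size_t)nx * ny);
    int rem = idx % ((size_t)nx * ny);
    int y = rem / nx, x = rem % nx;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          size_t nb = xx + (size_t)nx * (yy + (size_t)ny * zz);
          if (!acc[nb] && !queued[nb]) { queued[nb] = 1; q.push(nb); }
        }
  };
  for (size_t idx : init) push_nb(idx);
  while (!q.empty()) {
    size_t idx = q.front(); q.pop();
    int z = idx / ((size_t)nx * ny);
    int rem = idx % ((size_t)nx * ny);
    int y = rem / nx, x = rem % nx;
    // local stats of accepted voxels within radius r
    double s1 = 0, s2 = 0; int cnt = 0;
    for (int dz = -r; dz <= r; ++dz) {
      int zz = z + dz; if (zz < 0 || zz >= nz) continue;
      for (int dy = -r; dy <= r; ++dy) {
        int yy = y + dy; if (yy < 0 || yy >= ny) continue;
        for (int dx = -r; dx <= r; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          size_t nb = xx + (size_t)nx * (yy + (size_t)ny * zz);
          if (acc[nb]) { double v = vol[nb]; s1 += v; s2 += v * v; ++cnt; }
        }
      }
    }
    if (cnt == 0) continue;
    double m = s1 / cnt;
    double var = cnt > 1 ? (s2 - s1 * s1 / cnt) / (cnt - 1) : 0.0;
    double s = std::sqrt(std::max(var, 0.0));
    if (cnt < 8 || s <= 0) s = s_init;
    if (std::fabs(vol[idx] - m) <= k * s) {
      acc[idx] = true;
      push_nb(idx);
    }
  }
  return acc;
}

static void edt1d(std::vector<double> &f, std::vector<double> &d,
                  std::vector<int> &v, std::vector<double> &z, int n) {
  // Felzenszwalb & Huttenlocher lower-envelope distance transform (1D)
  int k = 0;
  v[0] = 0; z[0] = -1e30; z[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance transform (to nearest background voxel) of a
// binary mask, in voxel units.  Exact, separable.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector d(n);
  const double INF = 1e30;
  for (size_t i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      size_t off = (size_t)nx * (y + (size_t)ny * zz);
      for (int x = 0; x < nx; ++x) f[x] = d[off + x];
      edt1d(f, dd, v, z, nx);
      for (int x = 0; x < nx; ++x) d[off + x] = dd[x];
    }
  // y pass
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      size_t off = x + (size_t)nx * ny * zz;
      for (int y = 0; y < ny; ++y) f[y] = d[off + (size_t)nx * y];
      edt1d(f, dd, v, z, ny);
      for (int y = 0; y < ny; ++y) d[off + (size_t)nx * y] = dd[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      size_t off = x + (size_t)nx * y;
      size_t st = (size_t)nx * ny;
      for (int zz = 0; zz < nz; ++zz) f[zz] = d[off + st * zz];
      edt1d(f, dd, v, z, nz);
      for (int zz = 0; zz < nz; ++zz) d[off + st * zz] = dd[zz];
    }
  return d;
}

// Local thickness (maximum inscribed sphere): for every foreground voxel
// the diameter (in voxel units) of the largest sphere that contains the
// voxel and fits inside the mask.  radii: inscribed-sphere radius per
// voxel (voxel units, typically EDT - 0.5).  Sphere painting in
// decreasing radius order with the standard skip optimization.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector radii, LogicalVector mask,
                                  IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector lt(n);
  std::vector<size_t> idx;
  idx.reserve(n / 4);
  for (size_t i = 0; i < n; ++i) if (mask[i] && radii[i] > 0) idx.push_back(i);
  std::sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
    return radii[a] > radii[b];
  });
  for (size_t t = 0; t < idx.size(); ++t) {
    size_t c = idx[t];
    double R = radii[c];
    if (lt[c] >= 2.0 * R) continue;     // already covered by a larger sphere
    int z = c / ((size_t)nx * ny);
    int rem = c % ((size_t)nx * ny);
    int y = rem / nx, x = rem % nx;
    int ri = (int)std::floor(R);
    double R2 = R * R;
    for (int dz = -ri; dz <= ri; ++dz) {
      int zz = z + dz; if (zz < 0 || zz >= nz) continue;
      for (int dy = -ri; dy <= ri; ++dy) {
        int yy = y + dy; if (yy < 0 || yy >= ny) continue;
        double d2 = (double)dz * dz + (double)dy * dy;
        if (d2 > R2) continue;
        for (int dx = -ri; dx <= ri; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          if (d2 + dx * dx > R2) continue;
          size_t p = xx + (size_t)nx * (yy + (size_t)ny * zz);
          if (lt[p] < 2.0 * R) lt[p] = 2.0 * R;
        }
      }
    }
  }
  return lt;
}

// Connected component of seeds under 26-connectivity within a mask.
// [[Rcpp::export]]
LogicalVector cpp_flood_fill(LogicalVector mask, IntegerVector dim,
                             IntegerMatrix seeds) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  LogicalVector out(n);
  std::queue<size_t> q;
  for (int i = 0; i < seeds.nrow(); ++i) {
    size_t idx = (seeds(i, 0) - 1) +
      (size_t)nx * ((seeds(i, 1) - 1) + (size_t)ny * (seeds(i, 2) - 1));
    if (mask[idx] && !out[idx]) { out[idx] = true; q.push(idx); }
  }
  while (!q.empty()) {
    size_t idx = q.front(); q.pop();
    int z = idx / ((size_t)nx * ny);
    int rem = idx % ((size_t)nx * ny);
    int y = rem / nx, x = rem % nx;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          size_t nb = xx + (size_t)nx * (yy + (size_t)ny * zz);
          if (mask[nb] && !out[nb]) { out[nb] = true; q.push(nb); }
        }
  }
  return out;
}
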