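// Voxel-level kernels shared by the preprocessing, skeletonization and
// morphometry stages. All functions take volumes as flat vectors in R array
// order: dims = (nz, ny, nx), linear index = k + nz*(j + ny*i) (0-based),
// i.e. the z index varies fastest. World coordinates of voxel (k, j, i) are
// (k*dz, j*dy, i*dx) mm with spacing = (dz, dy, dx).
#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline void decompose(int idx, int nz, int ny, int &k, int &j, int &i) {
  k = idx % nz;
  int r = idx / nz;
  j = r % ny;
  i = r / ny;
}

// 1-D convolution along one axis with a symmetric-reflect boundary.
// axis: 1 = z, 2 = y, 3 = x.
// [[Rcpp::export]]
NumericVector convolve_axis_cpp(NumericVector x, IntegerVector dims,
                                NumericVector kernel, int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (x.size() != n) stop("volume size does not match dims");
  const int kl = kernel.size();
  const int r = (kl - 1) / 2;
  NumericVector out(n);

  int len, stride;
  if (axis == 1)      { len = nz; stride = 1; }
  else if (axis == 2) { len = ny; stride = nz; }
  else if (axis == 3) { len = nx; stride = nz * ny; }
  else stop("axis must be 1 (z), 2 (y) or 3 (x)");

  std::vector<double> line(len), res(len);
  // iterate over all lines along the chosen axis
  const int n_other1 = (axis == 1) ? ny : nz;
  const int n_other2 = (axis == 3) ? ny : nx;
  for (int b = 0; b < n_other1; ++b) {
    for (int c = 0; c < n_other2; ++c) {
      R_xlen_t base;
      if (axis == 1)      base = (R_xlen_t)nz * (b + (R_xlen_t)ny * c);
      else if (axis == 2) base = b + (R_xlen_t)nz * ny * c;
      else                base = b + (R_xlen_t)nz * c;
      for (int t = 0; t < len; ++t) line[t] = x[base + (R_xlen_t)t * stride];
      for (int t = 0; t < len; ++t) {
        double acc = 0.0;
        for (int u = -r; u <= r; ++u) {
          int m = t + u;
          while (m < 0 || m >= len) {      // reflect boundary
            if (m < 0) m = -m - 1;
            if (m >= len) m = 2 * len - m - 1;
          }
          acc += kernel[u + r] * line[m];
        }
        res[t] = acc;
      }
      for (int t = 0; t < len; ++t) out[base + (R_xlen_t)t * stride] = res[t];
    }
  }
  return out;
}

// Fill background cavities: any background component (6-connectivity) not
// reachable from the volume border becomes foreground.
// [[Rcpp::export]]
LogicalVector fill_holes_cpp(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("volume size does not match dims");
  std::vector<uint8_t> outside(n, 0);
  std::vector<int> stack;
  stack.reserve(1 << 16);
  // seed with all border background voxels
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        if (k > 0 && k < nz - 1 && j > 0 && j < ny - 1 && i > 0 && i < nx - 1)
          continue;
        R_xlen_t idx = k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i);
        if (!mask[idx] && !outside[idx]) { outside[idx] = 1; stack.push_back((int)idx); }
      }
  const int dzs[6] = {-1, 1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, -1, 1, 0, 0};
  const int dxs[6] = {0, 0, 0, 0, -1, 1};
  while (!stack.empty()) {
    int idx = stack.back(); stack.pop_back();
    int k, j, i; decompose(idx, nz, ny, k, j, i);
    for (int d = 0; d < 6; ++d) {
      int kk = k + dzs[d], jj = j + dys[d], ii = i + dxs[d];
      if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx) continue;
      R_xlen_t q = kk + (R_xlen_t)nz * (jj + (R_xlen_t)ny * ii);
      if (!mask[q] && !outside[q]) { outside[q] = 1; stack.push_back((int)q); }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = mask[t] || !outside[t];
  return out;
}

// Connected-component labeling of the foreground (connectivity 6 or 26).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("volume size does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int nextLab = 0;
  std::vector<int> dzs, dys, dxs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int man = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && man != 1) continue;
        dzs.push_back(dz); dys.push_back(dy); dxs.push_back(dx);
      }
  const int nd = (int)dzs.size();
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++nextLab;
    lab[s] = nextLab;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      int idx = stack.back(); stack.pop_back();
      int k, j, i; decompose(idx, nz, ny, k, j, i);
      for (int d = 0; d < nd; ++d) {
        int kk = k + dzs[d], jj = j + dys[d], ii = i + dxs[d];
        if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx) continue;
        R_xlen_t q = kk + (R_xlen_t)nz * (jj + (R_xlen_t)ny * ii);
        if (mask[q] && !lab[q]) { lab[q] = nextLab; stack.push_back((int)q); }
      }
    }
  }
  return lab;
}

// Anisotropic Euclidean distance transform (Felzenszwalb & Huttenlocher,
// separable lower-envelope scan per axis). Returns, for every foreground
// voxel, the distance in mm to the nearest background voxel centre;
// background voxels get 0.
// One lower-envelope scan over a line of squared distances. Two virtual
// zero-valued samples just outside the line (positions -1 and len) make
// voxels beyond the volume act as background at their would-be centres.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int len, double w2) {
  const int m = len + 2;              // samples at positions -1 .. len
  int k = 0;
  v[0] = -1;                          // left virtual background sample
  z[0] = -1e300;
  z[1] = 1e300;
  for (int qi = 1; qi < m; ++qi) {
    int q = qi - 1;
    double fq = (q < len) ? f[q] : 0.0;   // right virtual sample
    double s;
    while (true) {
      double fv = (v[k] < 0 || v[k] >= len) ? 0.0 : f[v[k]];
      s = ((fq + w2 * (double)q * q) - (fv + w2 * (double)v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (k > 0 && s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < len; ++q) {
    while (z[k + 1] < q) ++k;
    double fv = (v[k] < 0 || v[k] >= len) ? 0.0 : f[v[k]];
    d[q] = w2 * (double)(q - v[k]) * (q - v[k]) + fv;
  }
}

// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("volume size does not match dims");
  const double BIG = 1e30;
  std::vector<double> D(n);
  for (R_xlen_t t = 0; t < n; ++t) D[t] = mask[t] ? BIG : 0.0;

  const int lens[3] = {nz, ny, nx};
  const R_xlen_t strides[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  for (int axis = 0; axis < 3; ++axis) {
    const int len = lens[axis];
    const double w2 = spacing[axis] * spacing[axis];
    std::vector<double> f(len), d(len), z(len + 3);
    std::vector<int> v(len + 2);
    const int nA = (axis == 0) ? ny : nz;
    const int nB = (axis == 2) ? ny : nx;
    for (int a = 0; a < nA; ++a) {
      for (int b = 0; b < nB; ++b) {
        R_xlen_t base;
        if (axis == 0)      base = (R_xlen_t)nz * (a + (R_xlen_t)ny * b);
        else if (axis == 1) base = a + (R_xlen_t)nz * ny * b;
        else                base = a + (R_xlen_t)nz * b;
        for (int t = 0; t < len; ++t) f[t] = D[base + strides[axis] * t];
        dt1d(f, d, v, z, len, w2);
        for (int t = 0; t < len; ++t) D[base + strides[axis] * t] = d[t];
      }
    }
  }
  NumericVector out(n);
  for (R_xlen_t t = 0; t < n; ++t)
    out[t] = (D[t] >= 1e29) ? R_PosInf : std::sqrt(D[t]);
  return out;
}

// Detect whether any 2x2x2 block is entirely foreground (used to reject
// non-thin input to the skeleton graph builder).
// [[Rcpp::export]]
bool has_solid_block_cpp(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  for (int i = 0; i + 1 < nx; ++i)
    for (int j = 0; j + 1 < ny; ++j)
      for (int k = 0; k + 1 < nz; ++k) {
        bool all = true;
        for (int di = 0; di <= 1 && all; ++di)
          for (int dj = 0; dj <= 1 && all; ++dj)
            for (int dk = 0; dk <= 1 && all; ++dk) {
              R_xlen_t q = (k + dk) + (R_xlen_t)nz * ((j + dj) + (R_xlen_t)ny * (i + di));
              if (!mask[q]) all = false;
            }
        if (all) return true;
      }
  return false;
}

// 26-adjacency among a sorted set of voxel linear indices (1-based, as
// produced by which()). Returns an m x 2 matrix of 1-based positions into
// the input vector, each unordered pair once.
// [[Rcpp::export]]
IntegerMatrix voxel_adjacency_cpp(IntegerVector vox, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int m = vox.size();
  std::vector<int> idx0(m);
  for (int t = 0; t < m; ++t) idx0[t] = vox[t] - 1;
  std::vector<std::pair<int, int> > pairs;
  for (int t = 0; t < m; ++t) {
    int k, j, i; decompose(idx0[t], nz, ny, k, j, i);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dz == 0 && dy == 0 && dx == 0) continue;
          // visit each unordered pair once: positive lexicographic offsets
          if (dx < 0 || (dx == 0 && (dy < 0 || (dy == 0 && dz < 0)))) continue;
          int kk = k + dz, jj = j + dy, ii = i + dx;
          if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx) continue;
          int q = kk + nz * (jj + ny * ii);
          std::vector<int>::const_iterator it =
            std::lower_bound(idx0.begin(), idx0.end(), q);
          if (it != idx0.end() && *it == q)
            pairs.push_back(std::make_pair(t + 1, (int)(it - idx0.begin()) + 1));
        }
  }
  IntegerMatrix out((int)pairs.size(), 2);
  for (size_t t = 0; t < pairs.size(); ++t) {
    out(t, 0) = pairs[t].first;
    out(t, 1) = pairs[t].second;
  }
  return out;
}

// Rasterize tubes around polylines: voxel centres within radius of a
// branch polyline become foreground. polylines: list of Nx3 matrices with
// columns (x, y, z) in mm; diameters: one per polyline, in mm.
// [[Rcpp::export]]
LogicalVector voxelize_cpp(List polylines, NumericVector diameters,
                           IntegerVector dims, NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n, false);
  for (int b = 0; b < polylines.size(); ++b) {
    NumericMatrix P = polylines[b];
    const double r = diameters[b] / 2.0;
    const double r2 = r * r;
    for (int s = 0; s + 1 < P.nrow(); ++s) {
      double x0 = P(s, 0), y0 = P(s, 1), z0 = P(s, 2);
      double x1 = P(s + 1, 0), y1 = P(s + 1, 1), z1 = P(s + 1, 2);
      double vx = x1 - x0, vy = y1 - y0, vz = z1 - z0;
      double vv = vx * vx + vy * vy + vz * vz;
      int ilo = (int)std::ceil((std::min(x0, x1) - r) / dx - 1e-9);
      int ihi = (int)std::floor((std::max(x0, x1) + r) / dx + 1e-9);
      int jlo = (int)std::ceil((std::min(y0, y1) - r) / dy - 1e-9);
      int jhi = (int)std::floor((std::max(y0, y1) + r) / dy + 1e-9);
      int klo = (int)std::ceil((std::min(z0, z1) - r) / dz - 1e-9);
      int khi = (int)std::floor((std::max(z0, z1) + r) / dz + 1e-9);
      ilo = std::max(ilo, 0); ihi = std::min(ihi, nx - 1);
      jlo = std::max(jlo, 0); jhi = std::min(jhi, ny - 1);
      klo = std::max(klo, 0); khi = std::min(khi, nz - 1);
      for (int i = ilo; i <= ihi; ++i) {
        double px = i * dx - x0;
        for (int j = jlo; j <= jhi; ++j) {
          double py = j * dy - y0;
          for (int k = klo; k <= khi; ++k) {
            double pz = k * dz - z0;
            double t = (vv > 0) ? (px * vx + py * vy + pz * vz) / vv : 0.0;
            if (t < 0) t = 0; else if (t > 1) t = 1;
            double ex = px - t * vx, ey = py - t * vy, ez = pz - t * vz;
            if (ex * ex + ey * ey + ez * ez <= r2)
              out[k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i)] = true;
          }
        }
      }
    }
  }
  return out;
}

// Candidate contact point-pairs between branches: all cross-branch pairs of
// skeleton sample points whose centre distance is at most
// rad[p] + rad[q] + tol. Spatial hash grid; deterministic output order.
// [[Rcpp::export]]
DataFrame contact_candidates_cpp(NumericMatrix pts, NumericVector rad,
                                 IntegerVector branch, double tol) {
  const int n = pts.nrow();
  double rmax = 0.0;
  for (int t = 0; t < n; ++t) rmax = std::max(rmax, rad[t]);
  const double cell = std::max(2.0 * rmax + tol, 1.0);
  std::unordered_map<int64_t, std::vector<int> > grid;
  std::vector<int64_t> keys(n);
  const int64_t M = 1 << 21, OFF = 1 << 20;
  for (int t = 0; t < n; ++t) {
    int64_t cx = (int64_t)std::floor(pts(t, 0) / cell) + OFF;
    int64_t cy = (int64_t)std::floor(pts(t, 1) / cell) + OFF;
    int64_t cz = (int64_t)std::floor(pts(t, 2) / cell) + OFF;
    keys[t] = (cx * M + cy) * M + cz;
    grid[keys[t]].push_back(t);
  }
  std::vector<int> ia, ib;
  std::vector<double> dd;
  for (int p = 0; p < n; ++p) {
    int64_t cx = keys[p] / (M * M), cy = (keys[p] / M) % M, cz = keys[p] % M;
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          std::unordered_map<int64_t, std::vector<int> >::const_iterator it =
            grid.find(((cx + ox) * M + (cy + oy)) * M + (cz + oz));
          if (it == grid.end()) continue;
          const std::vector<int> &v = it->second;
          for (size_t u = 0; u < v.size(); ++u) {
            int q = v[u];
            if (q >= p || branch[q] == branch[p]) continue;
            double ex = pts(p, 0) - pts(q, 0);
            double ey = pts(p, 1) - pts(q, 1);
            double ez = pts(p, 2) - pts(q, 2);
            double d = std::sqrt(ex * ex + ey * ey + ez * ez);
            if (d <= rad[p] + rad[q] + tol) {
              ia.push_back(q + 1);
              ib.push_back(p + 1);
              dd.push_back(d);
            }
          }
        }
  }
  // deterministic order: by first index then second
  std::vector<int> ord(ia.size());
  for (size_t t = 0; t < ord.size(); ++t) ord[t] = (int)t;
  struct Cmp {
    const std::vector<int> *a, *b;
    bool operator()(int x, int y) const {
      if ((*a)[x] != (*a)[y]) return (*a)[x] < (*a)[y];
      return (*b)[x] < (*b)[y];
    }
  } cmp;
  cmp.a = &ia; cmp.b = &ib;
  std::sort(ord.begin(), ord.end(), cmp);
  IntegerVector oa(ia.size()), ob(ia.size());
  NumericVector od(ia.size());
  for (size_t t = 0; t < ord.size(); ++t) {
    oa[t] = ia[ord[t]];
    ob[t] = ib[ord[t]];
    od[t] = dd[ord[t]];
  }
  return DataFrame::create(_["ia"] = oa, _["ib"] = ob, _["dist"] = od);
}
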