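// Topology-preserving 3-D thinning to a 1-voxel-wide curve skeleton.
//
// Distance-ordered homotopic thinning: foreground voxels are visited in
// order of increasing distance-to-background (anisotropic Euclidean
// distance in mm, supplied by the caller), and deleted when deletion does
// not change the topology of either phase (simple points) and does not
// shorten a curve end (a deletable voxel must keep at least two foreground
// 26-neighbours). Ordering by world distance makes the erosion isotropic
// in physical units, so the skeleton stays on the medial axis even for
// strongly anisotropic voxels, and branch ends retract by roughly one
// local radius, which is the geometric extent of the medial curve.
//
// Simplicity uses the standard local characterization: exactly one
// 26-connected foreground component in the 26-neighbourhood, and exactly
// one 6-connected background component in the 18-neighbourhood that is
// face-adjacent to the voxel. Deletion is sequential (re-checked at pop
// time), so topology is preserved unconditionally; ties in distance are
// broken by voxel index, making the result deterministic.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>
#include <algorithm>
#include <cstdlib>
using namespace Rcpp;

namespace {

// cell id within the 3x3x3 neighbourhood: (dz+1)*9 + (dy+1)*3 + (dx+1)
const int CENTER = 13;
bool tables_ready = false;
std::vector<int> adj26[27];   // 26-adjacency between cells (center excluded)
std::vector<int> adj6[27];    // 6-adjacency between cells, restricted to N18
bool inN18[27];
bool isFace[27];

void build_tables() {
  if (tables_ready) return;
  for (int c = 0; c < 27; ++c) {
    int dz = c / 9 - 1, dy = (c / 3) % 3 - 1, dx = c % 3 - 1;
    int man = std::abs(dz) + std::abs(dy) + std::abs(dx);
    inN18[c] = (c != CENTER) && (man <= 2);
    isFace[c] = (man == 1);
  }
  for (int a = 0; a < 27; ++a) {
    if (a == CENTER) continue;
    int az = a / 9 - 1, ay = (a / 3) % 3 - 1, ax = a % 3 - 1;
    for (int b = 0; b < 27; ++b) {
      if (b == CENTER || b == a) continue;
      int bz = b / 9 - 1, by = (b / 3) % 3 - 1, bx = b % 3 - 1;
      int ddz = std::abs(az - bz), ddy = std::abs(ay - by), ddx = std::abs(ax - bx);
      if (ddz <= 1 && ddy <= 1 && ddx <= 1) adj26[a].push_back(b);
      if (inN18[a] && inN18[b] && ddz + ddy + ddx == 1) adj6[a].push_back(b);
    }
  }
  tables_ready = true;
}

inline int count_fg(const bool *nb) {
  int c = 0;
  for (int t = 0; t < 27; ++t)
    if (t != CENTER && nb[t]) ++c;
  return c;
}

bool is_simple(const bool *nb) {
  // exactly one 26-connected foreground component in N26*
  int seen[27] = {0};
  int comps = 0;
  int stack[27];
  for (int c = 0; c < 27; ++c) {
    if (c == CENTER || !nb[c] || seen[c]) continue;
    if (++comps > 1) return false;
    int top = 0;
    stack[top++] = c;
    seen[c] = 1;
    while (top) {
      int u = stack[--top];
      for (size_t t = 0; t < adj26[u].size(); ++t) {
        int v = adj26[u][t];
        if (v != CENTER && nb[v] && !seen[v]) { seen[v] = 1; stack[top++] = v; }
      }
    }
  }
  if (comps != 1) return false;
  // exactly one 6-connected background component in N18 touching a face
  int seenB[27] = {0};
  int bcomps = 0;
  for (int c = 0; c < 27; ++c) {
    if (!isFace[c] || nb[c] || seenB[c]) continue;
    if (++bcomps > 1) return false;
    int top = 0;
    stack[top++] = c;
    seenB[c] = 1;
    while (top) {
      int u = stack[--top];
      for (size_t t = 0; t < adj6[u].size(); ++t) {
        int v = adj6[u][t];
        if (!nb[v] && !seenB[v]) { seenB[v] = 1; stack[top++] = v; }
      }
    }
  }
  return bcomps == 1;
}

struct QItem {
  double dist;
  int idx;
  bool operator<(const QItem &o) const {
    if (dist != o.dist) return dist > o.dist;   // min-heap on distance
    return idx > o.idx;                          // then on index
  }
};

} // namespace

// vol: binary volume; dist: distance-to-background of the *original* mask
// (same length), typically from edt_cpp.
// [[Rcpp::export]]
LogicalVector thin_cpp(LogicalVector vol, IntegerVector dims,
                       NumericVector dist) {
  build_tables();
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (vol.size() != n) stop("volume size does not match dims");
  if (dist.size() != n) stop("distance map size does not match dims");
  std::vector<uint8_t> img(n);
  for (R_xlen_t t = 0; t < n; ++t) img[t] = vol[t] ? 1 : 0;

  std::priority_queue<QItem> pq;
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (!img[idx]) continue;
    int k = idx % nz, r = (int)(idx / nz), j = r % ny, i = r / ny;
    bool border = false;
    const int dzs[6] = {1, -1, 0, 0, 0, 0};
    const int dys[6] = {0, 0, 1, -1, 0, 0};
    const int dxs[6] = {0, 0, 0, 0, 1, -1};
    for (int d = 0; d < 6 && !border; ++d) {
      int kk = k + dzs[d], jj = j + dys[d], ii = i + dxs[d];
      border = (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx) ||
               !img[kk + (R_xlen_t)nz * (jj + (R_xlen_t)ny * ii)];
    }
    if (border) pq.push(QItem{dist[idx], (int)idx});
  }

  bool nbmask[27];
  while (!pq.empty()) {
    int idx = pq.top().idx;
    pq.pop();
    if (!img[idx]) continue;
    int k = idx % nz, r = idx / nz, j = r % ny, i = r / ny;
    for (int c = 0; c < 27; ++c) {
      int cz = c / 9 - 1, cy = (c / 3) % 3 - 1, cx = c % 3 - 1;
      int zk = k + cz, yj = j + cy, xi = i + cx;
      nbmask[c] = !(zk < 0 || zk >= nz || yj < 0 || yj >= ny || xi < 0 || xi >= nx) &&
                  img[zk + (R_xlen_t)nz * (yj + (R_xlen_t)ny * xi)];
    }
    if (count_fg(nbmask) < 2) continue;   // preserve curve endpoints
    if (!is_simple(nbmask)) continue;
    img[idx] = 0;
    // deletion exposes the 26-neighbourhood: requeue foreground neighbours
    for (int c = 0; c < 27; ++c) {
      if (c == CENTER || !nbmask[c]) continue;
      int cz = c / 9 - 1, cy = (c / 3) % 3 - 1, cx = c % 3 - 1;
      R_xlen_t q = (k + cz) + (R_xlen_t)nz * ((j + cy) + (R_xlen_t)ny * (i + cx));
      pq.push(QItem{dist[q], (int)q});
    }
  }

  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = img[t] != 0;
  return out;
}
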