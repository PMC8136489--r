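// Occupancy-grid primitives for cavity volumetrics: sphere rasterisation,
// 6-connected BFS (flood fill / bounded dilation) and component counting.

#include <Rcpp.h>
#include <queue>

using namespace Rcpp;

static inline int idx3(int i, int j, int k, const int* d) {
  return i + d[0] * (j + d[1] * k);
}

// mark voxels whose centre lies within r(a) of atom a
// [[Rcpp::export]]
LogicalVector occ_grid_mark(const NumericMatrix& xyz, const NumericVector& r,
                            const NumericVector& lo, double spacing,
                            const IntegerVector& dims) {
  int d[3] = {dims[0], dims[1], dims[2]};
  LogicalVector occ((R_xlen_t)d[0] * d[1] * d[2], false);
  for (int a = 0; a < xyz.nrow(); ++a) {
    double ra = r[a], ra2 = ra * ra;
    int i0 = std::max(0, (int)std::ceil((xyz(a, 0) - ra - lo[0]) / spacing));
    int i1 = std::min(d[0] - 1, (int)std::floor((xyz(a, 0) + ra - lo[0]) / spacing));
    int j0 = std::max(0, (int)std::ceil((xyz(a, 1) - ra - lo[1]) / spacing));
    int j1 = std::min(d[1] - 1, (int)std::floor((xyz(a, 1) + ra - lo[1]) / spacing));
    int k0 = std::max(0, (int)std::ceil((xyz(a, 2) - ra - lo[2]) / spacing));
    int k1 = std::min(d[2] - 1, (int)std::floor((xyz(a, 2) + ra - lo[2]) / spacing));
    for (int k = k0; k <= k1; ++k) {
      double dz = lo[2] + k * spacing - xyz(a, 2), dz2 = dz * dz;
      for (int j = j0; j <= j1; ++j) {
        double dy = lo[1] + j * spacing - xyz(a, 1), dy2 = dy * dy;
        if (dz2 + dy2 > ra2) continue;
        for (int i = i0; i <= i1; ++i) {
          double dx = lo[0] + i * spacing - xyz(a, 0);
          if (dx * dx + dy2 + dz2 <= ra2) occ[idx3(i, j, k, d)] = true;
        }
      }
    }
  }
  return occ;
}

// BFS over `free` voxels from `seed`; max_steps < 0 means unbounded
// (flood fill), otherwise the reached set is the seed grown by at most
// max_steps 6-connected steps (a Manhattan dilation when free is all-true).
// [[Rcpp::export]]
LogicalVector bfs_mask(const LogicalVector& free_vox,
                       const LogicalVector& seed, const IntegerVector& dims,
                       int max_steps) {
  int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  LogicalVector reach(n, false);
  std::vector<int> dist(n, -1);
  std::queue<int> q;
  for (R_xlen_t v = 0; v < n; ++v) {
    if (seed[v] && free_vox[v]) { reach[v] = true; dist[v] = 0; q.push((int)v); }
  }
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    int v = q.front(); q.pop();
    if (max_steps >= 0 && dist[v] >= max_steps) continue;
    int i = v % d[0], j = (v / d[0]) % d[1], k = v / (d[0] * d[1]);
    for (int t = 0; t < 6; ++t) {
      int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2])
        continue;
      int w = idx3(ii, jj, kk, d);
      if (!reach[w] && free_vox[w]) {
        reach[w] = true; dist[w] = dist[v] + 1; q.push(w);
      }
    }
  }
  return reach;
}

// Euclidean-ish dilation: voxels within chamfer distance max_dist (in voxel
// units) of the seed set, via Dijkstra over the 26-neighbourhood with step
// costs 1, sqrt(2), sqrt(3).
// [[Rcpp::export]]
LogicalVector chamfer_dilate(const LogicalVector& seed,
                             const IntegerVector& dims, double max_dist) {
  int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  std::vector<double> dist(n, -1.0);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (R_xlen_t v = 0; v < n; ++v)
    if (seed[v]) { dist[v] = 0.0; pq.push(Node(0.0, (int)v)); }
  const double c1 = 1.0, c2 = 1.4142135623730951, c3 = 1.7320508075688772;
  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    int v = top.second;
    if (top.first > dist[v]) continue;
    if (dist[v] >= max_dist) continue;
    int i = v % d[0], j = (v / d[0]) % d[1], k = v / (d[0] * d[1]);
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj)
        for (int dk = -1; dk <= 1; ++dk) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2])
            continue;
          int nd = std::abs(di) + std::abs(dj) + std::abs(dk);
          double step = nd == 1 ? c1 : (nd == 2 ? c2 : c3);
          double cand = dist[v] + step;
          if (cand > max_dist) continue;
          int w = idx3(ii, jj, kk, d);
          if (dist[w] < 0 || cand < dist[w]) {
            dist[w] = cand; pq.push(Node(cand, w));
          }
        }
  }
  LogicalVector out(n, false);
  for (R_xlen_t v = 0; v < n; ++v) out[v] = dist[v] >= 0;
  return out;
}

// number of 6-connected components of `mask` with at least min_voxels voxels
// [[Rcpp::export]]
int count_components_grid(const LogicalVector& mask, const IntegerVector& dims,
                          int min_voxels) {
  int d[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  std::vector<bool> seen(n, false);
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  int count = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || seen[s]) continue;
    int size = 0;
    std::queue<int> q;
    seen[s] = true; q.push((int)s);
    while (!q.empty()) {
      int v = q.front(); q.pop(); ++size;
      int i = v % d[0], j = (v / d[0]) % d[1], k = v / (d[0] * d[1]);
      for (int t = 0; t < 6; ++t) {
        int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2])
          continue;
        int w = idx3(ii, jj, kk, d);
        if (mask[w] && !seen[w]) { seen[w] = true; q.push(w); }
      }
    }
    if (size >= min_voxels) ++count;
  }
  return count;
}
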