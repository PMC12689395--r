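#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Greedy best-first search on the voxel lattice, 6-connectivity.
// Frontier ordered by Euclidean distance to the goal; FIFO among equal
// heuristics via an insertion counter; neighbors generated in the fixed
// order +x, -x, +y, -y, +z, -z. Blocked voxels (endocrine cells) are
// impassable. Coordinates are 0-based.

namespace {
struct Node {
  double h;
  long long order;
  int idx;
};
struct NodeCmp {
  bool operator()(const Node &a, const Node &b) const {
    if (a.h != b.h) return a.h > b.h; // min-heap on h
    return a.order > b.order;        // FIFO tie-break
  }
};
} // namespace

// [[Rcpp::export]]
List bfs_best_first_cpp(LogicalVector blocked, IntegerVector dims,
                        IntegerVector start, IntegerVector goal,
                        int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int *blk = LOGICAL(blocked);
  const int gi = goal[0], gj = goal[1], gk = goal[2];
  const int sidx = start[0] + nx * (start[1] + (R_xlen_t)ny * start[2]);
  const int gidx = gi + nx * (gj + (R_xlen_t)ny * gk);
  if (blk[sidx] || blk[gidx])
    stop("start and goal must be unoccupied (medium) voxels");

  std::vector<char> visited(n, 0);
  std::vector<int> parent(n, -1);
  std::priority_queue<Node, std::vector<Node>, NodeCmp> frontier;
  long long counter = 0;
  auto heur = [&](int i, int j, int k) {
    const double di = i - gi, dj = j - gj, dk = k - gk;
    return std::sqrt(di * di + dj * dj + dk * dk);
  };
  visited[sidx] = 1;
  frontier.push({heur(start[0], start[1], start[2]), counter++, sidx});
  // face neighbors first (+x,-x,+y,-y,+z,-z), then edge and corner moves
  // in a fixed documented order for 26-connectivity
  std::vector<int> vdi, vdj, vdk;
  {
    static const int fdi[6] = {1, -1, 0, 0, 0, 0};
    static const int fdj[6] = {0, 0, 1, -1, 0, 0};
    static const int fdk[6] = {0, 0, 0, 0, 1, -1};
    for (int d = 0; d < 6; ++d) {
      vdi.push_back(fdi[d]); vdj.push_back(fdj[d]); vdk.push_back(fdk[d]);
    }
    if (connectivity == 26) {
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int m = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (m < 2) continue;
            vdi.push_back(di); vdj.push_back(dj); vdk.push_back(dk);
          }
    }
  }
  const int n_dirs = (int)vdi.size();
  long long n_expanded = 0;
  bool found = false;
  while (!frontier.empty()) {
    Node cur = frontier.top();
    frontier.pop();
    ++n_expanded;
    if (cur.idx == gidx) {
      found = true;
      break;
    }
    const int ci = cur.idx % nx;
    const int cj = (cur.idx / nx) % ny;
    const int ck = cur.idx / (nx * ny);
    for (int d = 0; d < n_dirs; ++d) {
      const int i2 = ci + vdi[d], j2 = cj + vdj[d], k2 = ck + vdk[d];
      if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
        continue;
      const int idx2 = i2 + nx * (j2 + ny * k2);
      if (blk[idx2] || visited[idx2]) continue;
      visited[idx2] = 1;
      parent[idx2] = cur.idx;
      frontier.push({heur(i2, j2, k2), counter++, idx2});
    }
  }
  if (!found)
    return List::create(_["success"] = false,
                        _["voxels"] = IntegerMatrix(0, 3),
                        _["n_expanded"] = (double)n_expanded);
  std::vector<int> chain;
  for (int at = gidx; at != -1; at = parent[at]) chain.push_back(at);
  const int len = (int)chain.size();
  IntegerMatrix path(len, 3);
  for (int r = 0; r < len; ++r) {
    const int idx = chain[len - 1 - r]; // start -> goal
    path(r, 0) = idx % nx;
    path(r, 1) = (idx / nx) % ny;
    path(r, 2) = idx / (nx * ny);
  }
  return List::create(_["success"] = true, _["voxels"] = path,
                      _["n_expanded"] = (double)n_expanded);
}
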