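#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <queue>

using namespace Rcpp;

// Grid-bucketed DBSCAN for 2-D / 3-D point sets.
//
// Semantics (classic Ester et al., made fully deterministic):
//  * a point is core iff its *closed* eps-neighborhood, itself included,
//    holds >= min_pts points;
//  * clusters are the maximal density-connected sets of core points;
//  * a non-core (border) point joins the cluster of the lowest-index core
//    point within eps of it; unreachable points are noise;
//  * cluster labels are 0,1,2,... in order of each cluster's first core
//    point index; noise is -1.

namespace {

inline std::int64_t cell_key(const std::vector<int>& c, int d) {
  // pack up to 3 signed 21-bit cell coordinates into one 64-bit key
  std::int64_t k = 0;
  for (int a = 0; a < d; ++a)
    k = (k << 21) ^ ((std::int64_t)(c[a] + (1 << 20)) & 0x1FFFFF);
  return k;
}

} // namespace

// [[Rcpp::export(name = ".dbscan_labels_cpp")]]
IntegerVector dbscan_labels_cpp(NumericMatrix pts, double eps, int min_pts) {
  const int n = pts.nrow();
  const int d = pts.ncol();
  IntegerVector labels(n, -1);
  if (n == 0) return labels;
  if (d != 2 && d != 3) stop("points must be 2- or 3-dimensional");

  const double eps2 = eps * eps;

  // assign points to grid cells of side eps
  std::unordered_map<std::int64_t, std::vector<int>> grid;
  grid.reserve(n * 2);
  std::vector<std::vector<int>> cells(n, std::vector<int>(d));
  for (int i = 0; i < n; ++i) {
    for (int a = 0; a < d; ++a)
      cells[i][a] = (int)std::floor(pts(i, a) / eps);
    grid[cell_key(cells[i], d)].push_back(i);
  }

  // neighbor lists (closed neighborhoods, self included)
  std::vector<std::vector<int>> nb(n);
  std::vector<int> cc(d);
  for (int i = 0; i < n; ++i) {
    std::vector<int>& out = nb[i];
    const int lo = -1, hi = 1;
    if (d == 2) {
      for (int dx = lo; dx <= hi; ++dx)
        for (int dy = lo; dy <= hi; ++dy) {
          cc[0] = cells[i][0] + dx; cc[1] = cells[i][1] + dy;
          auto it = grid.find(cell_key(cc, d));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double a0 = pts(i, 0) - pts(j, 0);
            double a1 = pts(i, 1) - pts(j, 1);
            if (a0 * a0 + a1 * a1 <= eps2) out.push_back(j);
          }
        }
    } else {
      for (int dx = lo; dx <= hi; ++dx)
        for (int dy = lo; dy <= hi; ++dy)
          for (int dz = lo; dz <= hi; ++dz) {
            cc[0] = cells[i][0] + dx; cc[1] = cells[i][1] + dy;
            cc[2] = cells[i][2] + dz;
            auto it = grid.find(cell_key(cc, d));
            if (it == grid.end()) continue;
            for (int j : it->second) {
              double a0 = pts(i, 0) - pts(j, 0);
              double a1 = pts(i, 1) - pts(j, 1);
              double a2 = pts(i, 2) - pts(j, 2);
              if (a0 * a0 + a1 * a1 + a2 * a2 <= eps2) out.push_back(j);
            }
          }
    }
  }

  std::vector<bool> core(n, false);
  for (int i = 0; i < n; ++i) core[i] = (int)nb[i].size() >= min_pts;

  // label core points by BFS over density-connected cores,
  // seeded in increasing index order
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!core[i] || labels[i] >= 0) continue;
    int lab = next++;
    std::queue<int> q;
    labels[i] = lab;
    q.push(i);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int v : nb[u]) {
        if (core[v] && labels[v] < 0) {
          labels[v] = lab;
          q.push(v);
        }
      }
    }
  }

  // border points: lowest-index core neighbor decides
  for (int j = 0; j < n; ++j) {
    if (core[j]) continue;
    int best = -1;
    for (int v : nb[j])
      if (core[v] && (best < 0 || v < best)) best = v;
    if (best >= 0) labels[j] = labels[best];
  }

  return labels;
}
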