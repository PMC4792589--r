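#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Density clustering of 2D points (DBSCAN semantics): a core point has at
// least minNeighbors other points within eps; clusters are connected
// components of core points under distance <= eps, plus border points
// within eps of a core (assigned to the nearest core, ties to the lower
// point index). Neighbor queries use a uniform grid with cell size eps so
// only the 3x3 surrounding cells are scanned.
// Returned labels: -1 noise, otherwise 0-based cluster ids ordered by the
// smallest member index of each cluster.
// [[Rcpp::export(name = ".dbscan_labels")]]
IntegerVector dbscan_labels(NumericVector x, NumericVector y,
                            double eps, int minNeighbors) {
  const int n = x.size();
  IntegerVector labels(n, -1);
  if (n == 0) return labels;
  const double eps2 = eps * eps;

  double xmin = x[0], ymin = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (y[i] < ymin) ymin = y[i];
  }
  std::unordered_map<std::int64_t, std::vector<int>> grid;
  grid.reserve(n * 2);
  std::vector<std::int64_t> cellx(n), celly(n);
  for (int i = 0; i < n; ++i) {
    cellx[i] = (std::int64_t)std::floor((x[i] - xmin) / eps);
    celly[i] = (std::int64_t)std::floor((y[i] - ymin) / eps);
    grid[(cellx[i] << 32) ^ (celly[i] & 0xffffffffLL)].push_back(i);
  }

  std::vector<std::vector<int>> neigh(n);
  for (int i = 0; i < n; ++i) {
    for (std::int64_t cx = cellx[i] - 1; cx <= cellx[i] + 1; ++cx) {
      for (std::int64_t cy = celly[i] - 1; cy <= celly[i] + 1; ++cy) {
        auto it = grid.find((cx << 32) ^ (cy & 0xffffffffLL));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          if (j == i) continue;
          const double dx = x[i] - x[j], dy = y[i] - y[j];
          if (dx * dx + dy * dy <= eps2) neigh[i].push_back(j);
        }
      }
    }
  }

  std::vector<bool> core(n);
  for (int i = 0; i < n; ++i) core[i] = (int)neigh[i].size() >= minNeighbors;

  int next_id = 0;
  for (int i = 0; i < n; ++i) {
    if (!core[i] || labels[i] != -1) continue;
    const int id = next_id++;
    std::queue<int> q;
    labels[i] = id;
    q.push(i);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int v : neigh[u]) {
        if (core[v] && labels[v] == -1) {
          labels[v] = id;
          q.push(v);
        }
      }
    }
  }

  // border points: nearest core neighbor's cluster, ties to lower index
  for (int i = 0; i < n; ++i) {
    if (core[i] || labels[i] != -1) continue;
    double best = R_PosInf;
    int best_j = -1;
    for (int j : neigh[i]) {
      if (!core[j]) continue;
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best || (d2 == best && j < best_j)) {
        best = d2;
        best_j = j;
      }
    }
    if (best_j >= 0) labels[i] = labels[best_j];
  }

  // relabel so cluster ids are ordered by smallest member index
  std::vector<int> remap(next_id, -1);
  int out_id = 0;
  for (int i = 0; i < n; ++i) {
    if (labels[i] >= 0 && remap[labels[i]] == -1)
      remap[labels[i]] = out_id++;
  }
  for (int i = 0; i < n; ++i)
    if (labels[i] >= 0) labels[i] = remap[labels[i]];
  return labels;
}
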