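#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Multi-source Dijkstra over an 8-connected grid. cost is seconds per metre
// per cell (R_PosInf = impassable); step time between adjacent cells a,b is
// d(a,b) * (cost_a + cost_b) / 2 with d = cellSize orthogonally and
// cellSize * sqrt(2) diagonally. Returns seconds to the nearest source.
// [[Rcpp::export(name = ".dijkstraGrid")]]
NumericMatrix dijkstraGrid(NumericMatrix cost, IntegerMatrix sources,
                           double cellSize) {
  const int nr = cost.nrow(), nc = cost.ncol();
  const double inf = std::numeric_limits<double>::infinity();
  NumericMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), inf);

  typedef std::pair<double, int> Node;  // (distance, row + col * nr)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  for (int s = 0; s < sources.nrow(); ++s) {
    int r = sources(s, 0) - 1, c = sources(s, 1) - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("source cell outside the grid");
    if (!std::isfinite(cost(r, c))) continue;  // caller snaps or drops
    int id = r + c * nr;
    if (dist[id] > 0.0) {
      dist[id] = 0.0;
      pq.push(Node(0.0, id));
    }
  }
  if (pq.empty()) stop("no usable source on a finite-cost cell");

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double sqrt2 = std::sqrt(2.0);

  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    double d = top.first;
    int id = top.second;
    if (d > dist[id]) continue;
    int r = id % nr, c = id / nr;
    double ch = cost(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      double cn = cost(r2, c2);
      if (!std::isfinite(cn)) continue;
      double step = cellSize * ((dr[k] != 0 && dc[k] != 0) ? sqrt2 : 1.0);
      double nd = d + step * 0.5 * (ch + cn);
      int id2 = r2 + c2 * nr;
      if (nd < dist[id2]) {
        dist[id2] = nd;
        pq.push(Node(nd, id2));
      }
    }
  }
  return dist;
}
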