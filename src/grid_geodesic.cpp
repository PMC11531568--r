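#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Dijkstra shortest-path (geodesic) distances on a cubic grid with
// 26-neighbour connectivity. Nodes flagged as blocked are impassable.
// Distances are Euclidean step lengths in grid units times `spacing`.
// Returns Inf for blocked or unreachable nodes.
// [[Rcpp::export(name = ".grid_geodesic")]]
NumericVector grid_geodesic(int nx, int ny, int nz, LogicalVector blocked,
                            int source, double spacing) {
  const long n = (long)nx * ny * nz;
  if (blocked.size() != n) stop("blocked has wrong length");
  if (source < 0 || source >= n) stop("source index out of range");
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());

  // precompute the 26 neighbour offsets and their step lengths
  std::vector<int> dxs, dys, dzs;
  std::vector<double> w;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
        w.push_back(spacing * std::sqrt((double)(dx * dx + dy * dy + dz * dz)));
      }

  typedef std::pair<double, long> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  dist[source] = 0.0;
  pq.push(Node(0.0, source));

  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d = top.first;
    long u = top.second;
    if (d > dist[u]) continue;
    int ux = u % nx, uy = (u / nx) % ny, uz = u / ((long)nx * ny);
    for (size_t k = 0; k < w.size(); ++k) {
      int vx = ux + dxs[k], vy = uy + dys[k], vz = uz + dzs[k];
      if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz)
        continue;
      long v = vx + (long)nx * (vy + (long)ny * vz);
      if (blocked[v]) continue;
      double nd = d + w[k];
      if (nd < dist[v]) {
        dist[v] = nd;
        pq.push(Node(nd, v));
      }
    }
  }
  return NumericVector(dist.begin(), dist.end());
}
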