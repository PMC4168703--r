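// Minimum-cost flow by successive shortest paths (SPFA / Bellman-Ford queue).
// Costs may be negative (read-coverage bonuses); the input network is a DAG,
// so the zero flow is optimal for value 0 and the SSP invariant (no negative
// residual cycle) holds throughout. Capacities and costs are doubles holding
// integral values, exact up to 2^53.

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <limits>

using namespace Rcpp;

struct Arc {
  int to;
  double cap;
  double cost;
  int rev;      // index of reverse arc in graph[to]
  int orig;     // original edge index, -1 for reverse arcs
};

// [[Rcpp::export(name = ".mcf_solve_cpp")]]
List mcf_solve_cpp(int n, IntegerVector tail, IntegerVector head,
                   NumericVector cap, NumericVector cost,
                   int source, int sink, double k) {
  int m = tail.size();
  std::vector<std::vector<Arc>> g(n);
  std::vector<std::pair<int,int>> pos(m);
  for (int i = 0; i < m; ++i) {
    int u = tail[i] - 1, v = head[i] - 1;
    Arc a{v, cap[i], cost[i], (int)g[v].size(), i};
    Arc b{u, 0.0, -cost[i], (int)g[u].size(), -1};
    pos[i] = {u, (int)g[u].size()};
    g[u].push_back(a);
    g[v].push_back(b);
  }
  int s = source - 1, t = sink - 1;
  const double INF = std::numeric_limits<double>::infinity();
  double value = 0.0, total_cost = 0.0;
  std::vector<double> dist(n);
  std::vector<int> pv(n), pe(n);
  std::vector<char> inq(n);

  while (value < k) {
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(inq.begin(), inq.end(), 0);
    dist[s] = 0.0;
    std::deque<int> q;
    q.push_back(s); inq[s] = 1;
    while (!q.empty()) {
      int u = q.front(); q.pop_front(); inq[u] = 0;
      for (int j = 0; j < (int)g[u].size(); ++j) {
        const Arc &a = g[u][j];
        if (a.cap <= 0) continue;
        double nd = dist[u] + a.cost;
        if (nd < dist[a.to] - 1e-9) {
          dist[a.to] = nd;
          pv[a.to] = u; pe[a.to] = j;
          if (!inq[a.to]) {
            // SLF heuristic
            if (!q.empty() && nd < dist[q.front()]) q.push_front(a.to);
            else q.push_back(a.to);
            inq[a.to] = 1;
          }
        }
      }
    }
    if (dist[t] == INF) break;  // no augmenting path left
    // bottleneck along the path, limited by remaining demand
    double push = k - value;
    for (int v = t; v != s; v = pv[v]) {
      const Arc &a = g[pv[v]][pe[v]];
      if (a.cap < push) push = a.cap;
    }
    for (int v = t; v != s; v = pv[v]) {
      Arc &a = g[pv[v]][pe[v]];
      a.cap -= push;
      g[a.to][a.rev].cap += push;
    }
    value += push;
    total_cost += push * dist[t];
    Rcpp::checkUserInterrupt();
  }

  NumericVector flow(m);
  for (int i = 0; i < m; ++i) {
    const Arc &a = g[pos[i].first][pos[i].second];
    flow[i] = cap[i] - a.cap;
  }
  return List::create(_["flow"] = flow, _["cost"] = total_cost,
                      _["value"] = value);
}
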