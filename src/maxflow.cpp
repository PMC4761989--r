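#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Dinic max-flow on a directed graph with double capacities, plus a final
// residual BFS from the source, which yields the *minimal* source-side
// min-cut partition (deterministic; used both for the minimum-closed-set
// surface search and the segmentation graph cut).

namespace {

struct Dinic {
  int n;
  std::vector<int> to, nxt;
  std::vector<double> cap;
  std::vector<int> head;
  std::vector<int> level, it;
  static constexpr double EPS = 1e-11;

  explicit Dinic(int n_) : n(n_), head(n_, -1), level(n_), it(n_) {}

  void add_edge(int u, int v, double c, double rc) {
    to.push_back(v); cap.push_back(c); nxt.push_back(head[u]); head[u] = (int)to.size() - 1;
    to.push_back(u); cap.push_back(rc); nxt.push_back(head[v]); head[v] = (int)to.size() - 1;
  }

  bool bfs(int s, int t) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = head[u]; e != -1; e = nxt[e]) {
        if (cap[e] > EPS && level[to[e]] < 0) {
          level[to[e]] = level[u] + 1;
          q.push(to[e]);
        }
      }
    }
    return level[t] >= 0;
  }

  double dfs(int u, int t, double f) {
    if (u == t) return f;
    for (int &e = it[u]; e != -1; e = nxt[e]) {
      int v = to[e];
      if (cap[e] > EPS && level[v] == level[u] + 1) {
        double d = dfs(v, t, std::min(f, cap[e]));
        if (d > EPS) { cap[e] -= d; cap[e ^ 1] += d; return d; }
      }
    }
    return 0.0;
  }

  double run(int s, int t) {
    double flow = 0.0;
    while (bfs(s, t)) {
      for (int i = 0; i < n; ++i) it[i] = head[i];
      double f;
      while ((f = dfs(s, t, std::numeric_limits<double>::infinity())) > EPS)
        flow += f;
    }
    return flow;
  }

  LogicalVector source_side(int s) {
    LogicalVector side(n);
    std::vector<char> vis(n, 0);
    std::queue<int> q;
    vis[s] = 1; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = head[u]; e != -1; e = nxt[e])
        if (cap[e] > EPS && !vis[to[e]]) { vis[to[e]] = 1; q.push(to[e]); }
    }
    for (int i = 0; i < n; ++i) side[i] = vis[i] != 0;
    return side;
  }
};

} // namespace

// from/to are 1-based node ids in 1..n; cap/rcap are the forward and
// reverse capacities of each listed edge. Returns the max-flow value and
// the minimal source-side partition (residual reachability from s).
// [[Rcpp::export(name = ".maxflow_mincut")]]
List maxflow_mincut(int n, IntegerVector from, IntegerVector to,
                    NumericVector cap, NumericVector rcap, int s, int t) {
  Dinic d(n);
  R_xlen_t m = from.size();
  for (R_xlen_t i = 0; i < m; ++i)
    d.add_edge(from[i] - 1, to[i] - 1, cap[i], rcap.size() == m ? rcap[i] : 0.0);
  double value = d.run(s - 1, t - 1);
  return List::create(_["value"] = value, _["side"] = d.source_side(s - 1));
}
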