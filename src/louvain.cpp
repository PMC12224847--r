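#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Multilevel (Louvain) modularity optimizer with resolution parameter.
//
// Graph convention: undirected edge list, each edge once, 0-based endpoints,
// self-loops allowed (used internally by the aggregation phase). Weighted
// degree k_i counts a self-loop twice (A_ii = 2 * w_self), so that
// k_i = sum_j A_ij and Q = sum_c [ W_in(c)/m - gamma * (tot_c / 2m)^2 ].

namespace {

struct Graph {
  int n;
  std::vector<std::vector<std::pair<int, double>>> adj; // neighbor, weight
  std::vector<double> selfw;                            // self-loop weight
  std::vector<double> k;                                // weighted degree
  double m;                                             // total edge weight

  Graph(int n_, const std::vector<int>& ei, const std::vector<int>& ej,
        const std::vector<double>& ew)
      : n(n_), adj(n_), selfw(n_, 0.0), k(n_, 0.0), m(0.0) {
    for (size_t e = 0; e < ei.size(); ++e) {
      int i = ei[e], j = ej[e];
      double w = ew[e];
      m += w;
      if (i == j) {
        selfw[i] += w;
        k[i] += 2.0 * w;
      } else {
        adj[i].push_back({j, w});
        adj[j].push_back({i, w});
        k[i] += w;
        k[j] += w;
      }
    }
  }
};

double partition_q(const Graph& g, const std::vector<int>& memb, double gamma) {
  int nc = 0;
  for (int c : memb) nc = std::max(nc, c + 1);
  std::vector<double> win(nc, 0.0), tot(nc, 0.0);
  for (int i = 0; i < g.n; ++i) {
    tot[memb[i]] += g.k[i];
    win[memb[i]] += g.selfw[i];
    for (auto& nb : g.adj[i])
      if (memb[nb.first] == memb[i] && nb.first > i) win[memb[i]] += nb.second;
  }
  double q = 0.0, m2 = 2.0 * g.m;
  for (int c = 0; c < nc; ++c)
    q += win[c] / g.m - gamma * (tot[c] / m2) * (tot[c] / m2);
  return q;
}

// One local-moving phase; memb is modified in place. Returns true if any
// node changed community.
bool local_move(const Graph& g, std::vector<int>& memb, double gamma,
                std::mt19937& rng) {
  int n = g.n;
  double m2 = 2.0 * g.m;
  std::vector<double> tot(n, 0.0);
  for (int i = 0; i < n; ++i) tot[memb[i]] += g.k[i];

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> wlink(n, 0.0); // weight from node to community
  std::vector<int> touched;
  bool any_move = false, improved = true;
  while (improved) {
    improved = false;
    std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      int ci = memb[i];
      touched.clear();
      for (auto& nb : g.adj[i]) {
        int c = memb[nb.first];
        if (wlink[c] == 0.0) touched.push_back(c);
        wlink[c] += nb.second;
      }
      // remove i from its community
      tot[ci] -= g.k[i];
      double stay = wlink[ci] - gamma * g.k[i] * tot[ci] / m2;
      double best_gain = stay;
      int best_c = ci;
      for (int c : touched) {
        if (c == ci) continue;
        double gain = wlink[c] - gamma * g.k[i] * tot[c] / m2;
        // strict improvement over staying; ties among candidates -> lowest label
        if (gain > best_gain + 1e-12 ||
            (best_c != ci && std::abs(gain - best_gain) <= 1e-12 && c < best_c)) {
          best_gain = gain;
          best_c = c;
        }
      }
      tot[best_c] += g.k[i];
      if (best_c != ci) {
        memb[i] = best_c;
        improved = true;
        any_move = true;
      }
      for (int c : touched) wlink[c] = 0.0;
    }
  }
  return any_move;
}

void relabel(std::vector<int>& memb) {
  std::vector<int> map(memb.size(), -1);
  int next = 0;
  for (int& c : memb) {
    if (map[c] < 0) map[c] = next++;
    c = map[c];
  }
}

Graph aggregate(const Graph& g, const std::vector<int>& memb, int nc) {
  // accumulate edge weights between communities
  std::vector<std::vector<std::pair<int, double>>> acc(nc);
  std::vector<double> self(nc, 0.0);
  for (int i = 0; i < g.n; ++i) {
    self[memb[i]] += g.selfw[i];
    for (auto& nb : g.adj[i]) {
      if (nb.first <= i) continue;
      int a = memb[i], b = memb[nb.first];
      if (a == b) {
        self[a] += nb.second;
      } else {
        if (a > b) std::swap(a, b);
        acc[a].push_back({b, nb.second});
      }
    }
  }
  std::vector<int> ei, ej;
  std::vector<double> ew;
  for (int a = 0; a < nc; ++a) {
    if (self[a] > 0.0) {
      ei.push_back(a);
      ej.push_back(a);
      ew.push_back(self[a]);
    }
    std::sort(acc[a].begin(), acc[a].end());
    size_t s = 0;
    while (s < acc[a].size()) {
      size_t t = s;
      double w = 0.0;
      while (t < acc[a].size() && acc[a][t].first == acc[a][s].first)
        w += acc[a][t++].second;
      ei.push_back(a);
      ej.push_back(acc[a][s].first);
      ew.push_back(w);
      s = t;
    }
  }
  return Graph(nc, ei, ej, ew);
}

} // namespace

// [[Rcpp::export(name = ".louvain_cpp")]]
List louvain_cpp(int n, IntegerVector edge_i, IntegerVector edge_j,
                 NumericVector edge_w, double gamma, int seed) {
  std::vector<int> ei(edge_i.begin(), edge_i.end());
  std::vector<int> ej(edge_j.begin(), edge_j.end());
  std::vector<double> ew(edge_w.begin(), edge_w.end());
  Graph g(n, ei, ej, ew);
  if (g.m <= 0) stop("modularity is undefined on an edgeless graph");

  std::mt19937 rng(static_cast<unsigned>(seed));

  std::vector<int> global(n);
  for (int i = 0; i < n; ++i) global[i] = i;

  Graph cur = g;
  int levels = 0;
  std::vector<double> level_q;
  while (true) {
    std::vector<int> memb(cur.n);
    for (int i = 0; i < cur.n; ++i) memb[i] = i;
    bool moved = local_move(cur, memb, gamma, rng);
    relabel(memb);
    int nc = *std::max_element(memb.begin(), memb.end()) + 1;
    for (int i = 0; i < n; ++i) global[i] = memb[global[i]];
    ++levels;
    level_q.push_back(partition_q(g, global, gamma));
    if (!moved || nc == cur.n) break;
    cur = aggregate(cur, memb, nc);
  }

  relabel(global);
  double q = partition_q(g, global, gamma);
  return List::create(_["membership"] = IntegerVector(global.begin(), global.end()),
                      _["modularity"] = q,
                      _["levels"] = levels,
                      _["level_modularity"] = NumericVector(level_q.begin(), level_q.end()));
}

// [[Rcpp::export(name = ".modularity_cpp")]]
double modularity_cpp(int n, IntegerVector edge_i, IntegerVector edge_j,
                      NumericVector edge_w, IntegerVector membership,
                      double gamma) {
  std::vector<int> ei(edge_i.begin(), edge_i.end());
  std::vector<int> ej(edge_j.begin(), edge_j.end());
  std::vector<double> ew(edge_w.begin(), edge_w.end());
  Graph g(n, ei, ej, ew);
  if (g.m <= 0) stop("modularity is undefined on an edgeless graph");
  std::vector<int> memb(membership.begin(), membership.end());
  return partition_q(g, memb, gamma);
}
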