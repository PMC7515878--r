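// Core motif-statistic and simulation kernels for aggregation graphs.
//
// The nine sufficient statistics are, in fixed order:
//   0 e     edges
//   1 2s    two-stars, sum_v C(deg v, 2)
//   2 NSP1  non-adjacent pairs with exactly 1 common neighbour
//   3 NSP2  non-adjacent pairs with exactly 2 common neighbours
//   4 ESP0  adjacent pairs with exactly 0 common neighbours
//   5 ESP1  adjacent pairs with exactly 1 common neighbour
//   6 C5    simple 5-cycle subgraphs (edge sets, counted once each)
//   7 C6    simple 6-cycle subgraphs
//   8 C7    simple 7-cycle subgraphs
//
// All vertex indices at this level are 0-based; the R wrappers translate.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

namespace {

struct Graph {
  int n;
  std::vector<uint8_t> adj;           // n*n adjacency matrix
  std::vector<std::vector<int>> nbr;  // adjacency lists
  std::vector<int> deg;

  explicit Graph(int n_) : n(n_), adj((size_t)n_ * n_, 0), nbr(n_), deg(n_, 0) {}

  inline bool has(int u, int v) const { return adj[(size_t)u * n + v] != 0; }

  void add_edge(int u, int v) {
    adj[(size_t)u * n + v] = adj[(size_t)v * n + u] = 1;
    nbr[u].push_back(v);
    nbr[v].push_back(u);
    ++deg[u]; ++deg[v];
  }

  void remove_edge(int u, int v) {
    adj[(size_t)u * n + v] = adj[(size_t)v * n + u] = 0;
    drop(nbr[u], v);
    drop(nbr[v], u);
    --deg[u]; --deg[v];
  }

  static void drop(std::vector<int>& vec, int x) {
    for (size_t i = 0; i < vec.size(); ++i) {
      if (vec[i] == x) { vec[i] = vec.back(); vec.pop_back(); return; }
    }
  }
};

Graph build_graph(int n, const IntegerMatrix& edges0) {
  Graph g(n);
  for (int i = 0; i < edges0.nrow(); ++i) {
    int u = edges0(i, 0), v = edges0(i, 1);
    if (u < 0 || v < 0 || u >= n || v >= n || u == v)
      stop("invalid edge (%d, %d) for n = %d", u + 1, v + 1, n);
    if (!g.has(u, v)) g.add_edge(u, v);
  }
  return g;
}

// number of common neighbours of u and x
inline int common_neighbours(const Graph& g, int u, int x) {
  const std::vector<int>& a = (g.deg[u] <= g.deg[x]) ? g.nbr[u] : g.nbr[x];
  int other = (g.deg[u] <= g.deg[x]) ? x : u;
  int c = 0;
  for (int w : a) c += g.has(other, w);
  return c;
}

// Count simple paths from u to v of edge-length 4, 5 and 6 (never passing
// through v as an intermediate).  Cycles of length k through edge {u,v}
// correspond one-to-one with such paths of length k-1.
struct PathCounter {
  const Graph& g;
  int v;
  std::vector<uint8_t> visited;
  long cnt[3];
  PathCounter(const Graph& g_, int u, int v_) : g(g_), v(v_), visited(g_.n, 0) {
    cnt[0] = cnt[1] = cnt[2] = 0;
    visited[u] = 1;
    dfs(u, 0);
  }
  void dfs(int x, int depth) {
    for (int w : g.nbr[x]) {
      if (w == v) {
        if (depth + 1 >= 4) ++cnt[depth + 1 - 4];
        continue;
      }
      if (visited[w] || depth + 1 >= 6) continue;
      visited[w] = 1;
      dfs(w, depth + 1);
      visited[w] = 0;
    }
  }
};

void full_stats(const Graph& g, double out[9]) {
  for (int k = 0; k < 9; ++k) out[k] = 0.0;
  long e = 0, s2 = 0;
  for (int v = 0; v < g.n; ++v) {
    e += g.deg[v];
    s2 += (long)g.deg[v] * (g.deg[v] - 1) / 2;
  }
  e /= 2;
  out[0] = (double)e;
  out[1] = (double)s2;
  // shared-partner census over all pairs
  for (int i = 0; i < g.n; ++i) {
    for (int j = i + 1; j < g.n; ++j) {
      int c = common_neighbours(g, i, j);
      if (g.has(i, j)) {
        if (c == 0) out[4] += 1; else if (c == 1) out[5] += 1;
      } else {
        if (c == 1) out[2] += 1; else if (c == 2) out[3] += 1;
      }
    }
  }
  // cycle census: each k-cycle counted once per contained edge
  long c5 = 0, c6 = 0, c7 = 0;
  for (int u = 0; u < g.n; ++u) {
    for (int v : g.nbr[u]) {
      if (v <= u) continue;
      PathCounter pc(g, u, v);
      c5 += pc.cnt[0]; c6 += pc.cnt[1]; c7 += pc.cnt[2];
    }
  }
  out[6] = (double)(c5 / 5);
  out[7] = (double)(c6 / 6);
  out[8] = (double)(c7 / 7);
}

// Change statistics for ADDING edge {u,v} (must be absent): t(g+uv) - t(g).
void delta_add(const Graph& g, int u, int v, double d[9]) {
  for (int k = 0; k < 9; ++k) d[k] = 0.0;
  d[0] = 1.0;
  d[1] = (double)(g.deg[u] + g.deg[v]);
  // the dyad {u,v} moves from its NSP bin to an ESP bin
  int c = common_neighbours(g, u, v);
  if (c == 1) d[2] -= 1; else if (c == 2) d[3] -= 1;
  if (c == 0) d[4] += 1; else if (c == 1) d[5] += 1;
  // pairs {u,x} for x ~ v gain v as a shared partner; likewise {v,y} for y ~ u
  for (int side = 0; side < 2; ++side) {
    int a = side == 0 ? u : v;      // pair anchor
    int b = side == 0 ? v : u;      // its neighbours supply the partners
    for (int x : g.nbr[b]) {
      if (x == a) continue;
      int k = common_neighbours(g, a, x);
      if (g.has(a, x)) {
        if (k == 0) { d[4] -= 1; d[5] += 1; }
        else if (k == 1) { d[5] -= 1; }
      } else {
        if (k == 0) { d[2] += 1; }
        else if (k == 1) { d[2] -= 1; d[3] += 1; }
        else if (k == 2) { d[3] -= 1; }
      }
    }
  }
  // cycles created through the new edge
  PathCounter pc(g, u, v);
  d[6] = (double)pc.cnt[0];
  d[7] = (double)pc.cnt[1];
  d[8] = (double)pc.cnt[2];
}

// Change statistics for toggling dyad {u,v} in g (either direction).
void delta_toggle(Graph& g, int u, int v, double d[9]) {
  if (!g.has(u, v)) {
    delta_add(g, u, v, d);
  } else {
    g.remove_edge(u, v);
    delta_add(g, u, v, d);
    g.add_edge(u, v);
    for (int k = 0; k < 9; ++k) d[k] = -d[k];
  }
}

inline double toggle_rate(Graph& g, int u, int v, const double* coef,
                          double beta, double A) {
  double d[9];
  delta_toggle(g, u, v, d);
  double dH = 0.0;
  for (int k = 0; k < 9; ++k) dH += coef[k] * d[k];
  return A / (1.0 + std::exp(beta * dH));
}

inline int dyad_index(int n, int u, int v) {
  // u < v, 0-based, lexicographic over (u, v)
  return u * n - u * (u + 1) / 2 + (v - u - 1);
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_sufficient_stats(int n, IntegerMatrix edges0) {
  Graph g = build_graph(n, edges0);
  double out[9];
  full_stats(g, out);
  return NumericVector(out, out + 9);
}

// [[Rcpp::export]]
NumericVector cpp_change_stats(int n, IntegerMatrix edges0, int u0, int v0) {
  Graph g = build_graph(n, edges0);
  double d[9];
  delta_toggle(g, u0, v0, d);
  return NumericVector(d, d + 9);
}

// [[Rcpp::export]]
NumericVector cpp_all_rates(int n, IntegerMatrix edges0, NumericVector coef,
                            double beta, double A) {
  Graph g = build_graph(n, edges0);
  int ndyad = n * (n - 1) / 2;
  NumericVector out(ndyad);
  int k = 0;
  for (int u = 0; u < n; ++u)
    for (int v = u + 1; v < n; ++v)
      out[k++] = toggle_rate(g, u, v, coef.begin(), beta, A);
  return out;
}

// Metropolis-Hastings over uniform single-dyad toggles.
// record: 0 = none, 1 = graph codes (requires n <= 7), 2 = edge matrices
// [[Rcpp::export]]
List cpp_mcmc(int n, NumericVector coef, double beta, double steps_d,
              double burnin_d, double thin_d, int record) {
  RNGScope scope;
  long steps = (long)steps_d, burnin = (long)burnin_d, thin = (long)thin_d;
  if (thin < 1) thin = 1;
  int ndyad = n * (n - 1) / 2;
  if (record == 1 && ndyad > 31) stop("graph codes require n <= 8");
  Graph g(n);
  std::vector<std::pair<int,int>> dyads(ndyad);
  {
    int k = 0;
    for (int u = 0; u < n; ++u)
      for (int v = u + 1; v < n; ++v) dyads[k++] = {u, v};
  }
  long code = 0;
  std::vector<int> codes;
  List graphs;
  long nrec_est = record ? (steps - burnin) / thin + 1 : 0;
  if (record == 1) codes.reserve(nrec_est);
  long accepted = 0;
  for (long step = 1; step <= steps; ++step) {
    int k = (int)(unif_rand() * ndyad);
    if (k >= ndyad) k = ndyad - 1;
    int u = dyads[k].first, v = dyads[k].second;
    double d[9];
    delta_toggle(g, u, v, d);
    double dH = 0.0;
    for (int j = 0; j < 9; ++j) dH += coef[j] * d[j];
    double logacc = -beta * dH;
    if (logacc >= 0.0 || unif_rand() < std::exp(logacc)) {
      if (g.has(u, v)) { g.remove_edge(u, v); code &= ~(1L << k); }
      else { g.add_edge(u, v); code |= (1L << k); }
      ++accepted;
    }
    if (record && step > burnin && (step - burnin) % thin == 0) {
      if (record == 1) {
        codes.push_back((int)code);
      } else {
        int ne = 0;
        for (int x = 0; x < n; ++x) ne += g.deg[x];
        ne /= 2;
        IntegerMatrix em(ne, 2);
        int r = 0;
        for (int x = 0; x < n; ++x)
          for (int y : g.nbr[x])
            if (y > x) { em(r, 0) = x; em(r, 1) = y; ++r; }
        graphs.push_back(em);
      }
    }
  }
  int ne = 0;
  for (int x = 0; x < n; ++x) ne += g.deg[x];
  ne /= 2;
  IntegerMatrix fin(ne, 2);
  int r = 0;
  for (int x = 0; x < n; ++x)
    for (int y : g.nbr[x])
      if (y > x) { fin(r, 0) = x; fin(r, 1) = y; ++r; }
  List out = List::create(_["final"] = fin, _["accepted"] = (double)accepted);
  if (record == 1) out["codes"] = IntegerVector(codes.begin(), codes.end());
  if (record == 2) out["graphs"] = graphs;
  return out;
}

// Continuous-time kinetic simulation from the empty graph.
//
// Per event: waiting time ~ Exp(R_total), then the realised toggle is drawn
// with probability rate/R_total (cumulative scan in fixed dyad order).  Rates
// are either recomputed for every dyad after each event (naive = true) or
// only for dyads whose change statistics can have been affected by the
// toggle: dyads incident to a toggled endpoint, or whose endpoint distances
// to the set {u,v} sum to at most 5 (the reach of the shared-partner and
// <=7-cycle terms).  Both modes produce bit-identical event streams.
// [[Rcpp::export]]
List cpp_simulate(int n, NumericVector coef, double beta, double A,
                  double max_events_d, double max_time, bool naive) {
  RNGScope scope;
  long max_events = (long)max_events_d;
  int ndyad = n * (n - 1) / 2;
  Graph g(n);
  std::vector<std::pair<int,int>> dyads(ndyad);
  {
    int k = 0;
    for (int u = 0; u < n; ++u)
      for (int v = u + 1; v < n; ++v) dyads[k++] = {u, v};
  }
  std::vector<double> rate(ndyad);
  for (int k = 0; k < ndyad; ++k)
    rate[k] = toggle_rate(g, dyads[k].first, dyads[k].second, coef.begin(), beta, A);

  std::vector<double> ev_time;
  std::vector<int> ev_u, ev_v, ev_add;
  std::vector<int> dist(n);
  std::queue<int> bfs;
  double t = 0.0;
  long nev = 0;
  while (true) {
    if (max_events > 0 && nev >= max_events) break;
    double total = 0.0;
    for (int k = 0; k < ndyad; ++k) total += rate[k];
    if (total <= 0.0) break;
    double wait = exp_rand() / total;
    if (max_time > 0 && t + wait > max_time) break;
    t += wait;
    double target = unif_rand() * total;
    int k = ndyad - 1;
    double cum = 0.0;
    for (int j = 0; j < ndyad; ++j) {
      cum += rate[j];
      if (target <= cum) { k = j; break; }
    }
    int u = dyads[k].first, v = dyads[k].second;
    bool adding = !g.has(u, v);
    if (adding) g.add_edge(u, v); else g.remove_edge(u, v);
    ev_time.push_back(t);
    ev_u.push_back(u);
    ev_v.push_back(v);
    ev_add.push_back(adding ? 1 : 0);
    ++nev;
    if (naive) {
      for (int j = 0; j < ndyad; ++j)
        rate[j] = toggle_rate(g, dyads[j].first, dyads[j].second, coef.begin(), beta, A);
    } else {
      // BFS distances to the set {u, v}, capped at 5
      std::fill(dist.begin(), dist.end(), -1);
      dist[u] = 0; dist[v] = 0;
      bfs.push(u); bfs.push(v);
      while (!bfs.empty()) {
        int x = bfs.front(); bfs.pop();
        if (dist[x] >= 5) continue;
        for (int w : g.nbr[x]) {
          if (dist[w] < 0) { dist[w] = dist[x] + 1; bfs.push(w); }
        }
      }
      for (int j = 0; j < ndyad; ++j) {
        int a = dyads[j].first, b = dyads[j].second;
        bool hit = (a == u || a == v || b == u || b == v);
        if (!hit && dist[a] >= 0 && dist[b] >= 0 && dist[a] + dist[b] <= 5)
          hit = true;
        if (hit)
          rate[j] = toggle_rate(g, a, b, coef.begin(), beta, A);
      }
    }
    if (nev % 4096 == 0) checkUserInterrupt();
  }
  return List::create(
    _["time"] = NumericVector(ev_time.begin(), ev_time.end()),
    _["u"] = IntegerVector(ev_u.begin(), ev_u.end()),
    _["v"] = IntegerVector(ev_v.begin(), ev_v.end()),
    _["add"] = IntegerVector(ev_add.begin(), ev_add.end()),
    _["end_time"] = t);
}
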