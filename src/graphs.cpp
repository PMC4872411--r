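#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Breadth-first-search hop distances from every source. Unreachable pairs
// are returned as NA so the R side can apply the reachable-pairs convention.
// [[Rcpp::export]]
IntegerMatrix bfs_distances_cpp(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j) != 0 && i != j) nb[i].push_back(j);

  IntegerMatrix d(n, n);
  std::fill(d.begin(), d.end(), NA_INTEGER);
  std::vector<int> queue_(n);
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    int head = 0, tail = 0;
    queue_[tail++] = s;
    while (head < tail) {
      int u = queue_[head++];
      for (size_t k = 0; k < nb[u].size(); ++k) {
        int v = nb[u][k];
        if (dist[v] < 0) {
          dist[v] = dist[u] + 1;
          queue_[tail++] = v;
        }
      }
    }
    for (int j = 0; j < n; ++j)
      if (dist[j] >= 0) d(s, j) = dist[j];
  }
  return d;
}

static double subgraph_global_efficiency(const std::vector<int>& nodes,
                                         const IntegerMatrix& adj) {
  const int k = (int) nodes.size();
  if (k < 2) return 0.0;
  // BFS restricted to the induced subgraph
  std::vector<std::vector<int> > nb(k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      if (i != j && adj(nodes[i], nodes[j]) != 0) nb[i].push_back(j);
  double sum = 0.0;
  std::vector<int> dist(k), queue_(k);
  for (int s = 0; s < k; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    int head = 0, tail = 0;
    queue_[tail++] = s;
    while (head < tail) {
      int u = queue_[head++];
      for (size_t t = 0; t < nb[u].size(); ++t) {
        int v = nb[u][t];
        if (dist[v] < 0) { dist[v] = dist[u] + 1; queue_[tail++] = v; }
      }
    }
    for (int j = 0; j < k; ++j)
      if (j != s && dist[j] > 0) sum += 1.0 / dist[j];
  }
  return sum / ((double) k * (k - 1));
}

// Mean over nodes of the global efficiency of the neighbourhood subgraph
// (the node itself excluded); nodes with fewer than 2 neighbours contribute 0.
// [[Rcpp::export]]
double local_efficiency_cpp(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  if (n == 0) return 0.0;
  double total = 0.0;
  std::vector<int> nbrs;
  for (int i = 0; i < n; ++i) {
    nbrs.clear();
    for (int j = 0; j < n; ++j)
      if (j != i && adj(i, j) != 0) nbrs.push_back(j);
    if (nbrs.size() >= 2) total += subgraph_global_efficiency(nbrs, adj);
  }
  return total / n;
}

// ---- motif census -------------------------------------------------------
// Classes (fixed catalogue order):
// 1 path3, 2 triangle, 3 path4, 4 star4, 5 cycle4, 6 paw, 7 diamond, 8 K4.
// Connected induced subgraphs on 3 and 4 vertices are enumerated once each
// with the ESU algorithm; classification is by edge count plus maximum
// degree, which separates all eight classes.

static int classify_subset(const std::vector<int>& sub, const IntegerMatrix& adj) {
  const int k = (int) sub.size();
  int ecount = 0;
  int deg[4] = {0, 0, 0, 0};
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j)
      if (adj(sub[i], sub[j]) != 0) { ++ecount; ++deg[i]; ++deg[j]; }
  int maxdeg = 0;
  for (int i = 0; i < k; ++i) if (deg[i] > maxdeg) maxdeg = deg[i];
  if (k == 3) {
    if (ecount == 2) return 0;          // path3
    if (ecount == 3) return 1;          // triangle
    return -1;                          // disconnected (ESU never yields this)
  }
  switch (ecount) {
    case 3: return maxdeg == 3 ? 3 : 2; // star4 : path4
    case 4: return maxdeg == 3 ? 5 : 4; // paw : cycle4
    case 5: return 6;                   // diamond
    case 6: return 7;                   // K4
    default: return -1;
  }
}

static inline int classify_fast(const int* sub, int k, const int* a, int n) {
  int ecount = 0;
  int deg[4] = {0, 0, 0, 0};
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j)
      if (a[sub[i] + (size_t) n * sub[j]] != 0) { ++ecount; ++deg[i]; ++deg[j]; }
  int maxdeg = deg[0];
  for (int i = 1; i < k; ++i) if (deg[i] > maxdeg) maxdeg = deg[i];
  if (k == 3) return ecount == 2 ? 0 : (ecount == 3 ? 1 : -1);
  switch (ecount) {
    case 3: return maxdeg == 3 ? 3 : 2;
    case 4: return maxdeg == 3 ? 5 : 4;
    case 5: return 6;
    case 6: return 7;
    default: return -1;
  }
}

struct EsuCtx {
  const int* a;
  int n;
  int k;
  const std::vector<std::vector<int> >* nb;
  long long* counts;
  int sub[4];
  int depth;
};

static void esu_extend(EsuCtx& cx, std::vector<int>& ext, int v) {
  const std::vector<std::vector<int> >& nb = *cx.nb;
  if (cx.depth + 1 == cx.k) {
    // leaf level: each remaining extension vertex completes one subgraph
    for (size_t t = 0; t < ext.size(); ++t) {
      cx.sub[cx.depth] = ext[t];
      int cls = classify_fast(cx.sub, cx.k, cx.a, cx.n);
      if (cls >= 0) ++cx.counts[cls];
    }
    return;
  }
  std::vector<int> ext2;
  while (!ext.empty()) {
    int w = ext.back();
    ext.pop_back();
    ext2.assign(ext.begin(), ext.end());
    for (size_t t = 0; t < nb[w].size(); ++t) {
      int u = nb[w][t];
      if (u <= v) continue;
      bool skip = false;
      for (int i = 0; i < cx.depth && !skip; ++i)
        if (u == cx.sub[i] || cx.a[u + (size_t) cx.n * cx.sub[i]] != 0)
          skip = true;  // in sub, or adjacent to sub (not exclusive)
      if (skip) continue;
      for (size_t i = 0; i < ext.size() && !skip; ++i)
        if (ext[i] == u) skip = true;
      if (!skip) ext2.push_back(u);
    }
    cx.sub[cx.depth] = w;
    ++cx.depth;
    esu_extend(cx, ext2, v);
    --cx.depth;
  }
}

static void esu_census(int k, const IntegerMatrix& adj,
                       const std::vector<std::vector<int> >& nb,
                       long long* counts) {
  const int n = adj.nrow();
  EsuCtx cx;
  cx.a = adj.begin();
  cx.n = n;
  cx.k = k;
  cx.nb = &nb;
  cx.counts = counts;
  std::vector<int> ext;
  for (int v = 0; v < n; ++v) {
    ext.clear();
    for (size_t t = 0; t < nb[v].size(); ++t)
      if (nb[v][t] > v) ext.push_back(nb[v][t]);
    cx.sub[0] = v;
    cx.depth = 1;
    esu_extend(cx, ext, v);
  }
}

// [[Rcpp::export]]
NumericVector motif_census_cpp(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j) != 0) nb[i].push_back(j);
  long long counts[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  esu_census(3, adj, nb, counts);
  esu_census(4, adj, nb, counts);
  NumericVector out(8);
  for (int i = 0; i < 8; ++i) out[i] = (double) counts[i];
  return out;
}

// L (reachable-pairs mean), unreachable ordered-pair count, and global
// efficiency in a single BFS pass.
// [[Rcpp::export]]
NumericVector path_stats_cpp(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j) != 0) nb[i].push_back(j);
  double sumd = 0, suminv = 0;
  long long reach = 0;
  std::vector<int> dist(n), queue_(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    int head = 0, tail = 0;
    queue_[tail++] = s;
    while (head < tail) {
      int u = queue_[head++];
      for (size_t t = 0; t < nb[u].size(); ++t) {
        int v = nb[u][t];
        if (dist[v] < 0) { dist[v] = dist[u] + 1; queue_[tail++] = v; }
      }
    }
    for (int j = 0; j < n; ++j)
      if (j != s && dist[j] > 0) {
        sumd += dist[j];
        suminv += 1.0 / dist[j];
        ++reach;
      }
  }
  long long pairs = (long long) n * (n - 1);
  NumericVector out(4);
  out[0] = reach > 0 ? sumd / reach : NA_REAL;     // L over reachable pairs
  out[1] = (double) (pairs - reach);               // unreachable ordered pairs
  out[2] = pairs > 0 ? suminv / pairs : 0.0;       // global efficiency
  out[3] = (double) reach;
  return out;
}

// ---- degree-preserving rewiring -----------------------------------------
// Double-edge swaps a-b, c-d -> a-d, c-b accepted only when the four
// vertices are distinct and neither replacement edge already exists.
// `attempts` swaps are attempted (not accepted); uses R's RNG.
// [[Rcpp::export]]
List rewire_cpp(const IntegerMatrix& edges, int n_nodes, int attempts) {
  const int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  std::vector<char> has((size_t) n_nodes * n_nodes, 0);
  for (int i = 0; i < m; ++i) {
    ea[i] = edges(i, 0);
    eb[i] = edges(i, 1);
    has[(size_t) ea[i] * n_nodes + eb[i]] = 1;
    has[(size_t) eb[i] * n_nodes + ea[i]] = 1;
  }
  long long accepted = 0;
  for (int it = 0; it < attempts; ++it) {
    int e1 = (int) (unif_rand() * m);
    int e2 = (int) (unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    // proposed: a-d, c-b
    if (a == c || a == d || b == c || b == d) continue;
    if (has[(size_t) a * n_nodes + d] || has[(size_t) c * n_nodes + b]) continue;
    has[(size_t) a * n_nodes + b] = has[(size_t) b * n_nodes + a] = 0;
    has[(size_t) c * n_nodes + d] = has[(size_t) d * n_nodes + c] = 0;
    has[(size_t) a * n_nodes + d] = has[(size_t) d * n_nodes + a] = 1;
    has[(size_t) c * n_nodes + b] = has[(size_t) b * n_nodes + c] = 1;
    ea[e1] = a; eb[e1] = d;
    ea[e2] = c; eb[e2] = b;
    ++accepted;
  }
  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) { out(i, 0) = ea[i]; out(i, 1) = eb[i]; }
  return List::create(_["edges"] = out, _["accepted"] = (double) accepted,
                      _["attempted"] = (double) attempts);
}
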