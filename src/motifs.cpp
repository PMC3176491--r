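#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <random>
using namespace Rcpp;

static inline long long pair_key(int a, int b, int n) {
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return (long long)lo * (long long)n + (long long)hi;
}

// Double-edge-switch Markov chain on one sign class of a simple signed
// graph. Node ids are 0-based. (ea, eb) are the switched edges; (fa, fb)
// are fixed forbidden pairs (the other sign class): a proposed edge landing
// on an occupied pair of either sign is rejected, keeping the graph simple
// with at most one edge per pair across signs. Each attempt picks two
// distinct edges and a random pairing of endpoints (symmetric proposal), so
// the chain's stationary distribution is uniform over the simple graphs
// with this sign's degree sequence that avoid the forbidden pairs.
// [[Rcpp::export]]
List switch_edges_cpp(IntegerVector ea, IntegerVector eb,
                      IntegerVector fa, IntegerVector fb,
                      int n_nodes, int attempts, int seed) {
  int m = ea.size();
  std::vector<int> A(ea.begin(), ea.end()), B(eb.begin(), eb.end());
  std::unordered_set<long long> occ;
  occ.reserve((m + fa.size()) * 2);
  for (int i = 0; i < m; ++i) occ.insert(pair_key(A[i], B[i], n_nodes));
  for (int i = 0; i < fa.size(); ++i)
    occ.insert(pair_key(fa[i], fb[i], n_nodes));
  int rejected = 0;
  if (m >= 2) {
    std::mt19937 rng((uint32_t)seed);
    std::uniform_int_distribution<int> pick(0, m - 1);
    std::uniform_int_distribution<int> coin(0, 1);
    for (int t = 0; t < attempts; ++t) {
      int i = pick(rng), j = pick(rng);
      if (i == j) { ++rejected; continue; }
      int a1 = A[i], b1 = B[i], a2 = A[j], b2 = B[j];
      // two possible rewirings; choose one uniformly
      int na1, nb1, na2, nb2;
      if (coin(rng)) { na1 = a1; nb1 = b2; na2 = a2; nb2 = b1; }
      else           { na1 = a1; nb1 = a2; na2 = b1; nb2 = b2; }
      if (na1 == nb1 || na2 == nb2) { ++rejected; continue; }
      long long k1 = pair_key(na1, nb1, n_nodes);
      long long k2 = pair_key(na2, nb2, n_nodes);
      long long o1 = pair_key(a1, b1, n_nodes);
      long long o2 = pair_key(a2, b2, n_nodes);
      if (k1 == k2) { ++rejected; continue; }
      bool clash1 = (k1 != o1 && k1 != o2 && occ.count(k1));
      bool clash2 = (k2 != o1 && k2 != o2 && occ.count(k2));
      if (clash1 || clash2) { ++rejected; continue; }
      occ.erase(o1); occ.erase(o2);
      occ.insert(k1); occ.insert(k2);
      A[i] = na1; B[i] = nb1; A[j] = na2; B[j] = nb2;
    }
  } else {
    rejected = attempts;
  }
  return List::create(_["gene_a"] = IntegerVector(A.begin(), A.end()),
                      _["gene_b"] = IntegerVector(B.begin(), B.end()),
                      _["rejected"] = rejected);
}

// Enumerate all triangles of a simple graph given by an edge list with
// 1-based node ids. Returns an integer matrix with one row per triangle,
// node ids ascending within a row.
// [[Rcpp::export]]
IntegerMatrix triangles_cpp(int n_nodes, IntegerVector ea, IntegerVector eb) {
  int m = ea.size();
  // forward adjacency: for u, neighbours v > u, sorted
  std::vector<std::vector<int>> fadj(n_nodes + 1);
  for (int i = 0; i < m; ++i) {
    int a = ea[i], b = eb[i];
    if (a > b) std::swap(a, b);
    fadj[a].push_back(b);
  }
  for (int u = 1; u <= n_nodes; ++u)
    std::sort(fadj[u].begin(), fadj[u].end());
  std::vector<int> t1, t2, t3;
  for (int u = 1; u <= n_nodes; ++u) {
    const std::vector<int>& nu = fadj[u];
    for (size_t vi = 0; vi < nu.size(); ++vi) {
      int v = nu[vi];
      const std::vector<int>& nv = fadj[v];
      // intersect nu (entries > v) with nv
      size_t p = vi + 1, q = 0;
      while (p < nu.size() && q < nv.size()) {
        if (nu[p] < nv[q]) ++p;
        else if (nu[p] > nv[q]) ++q;
        else {
          t1.push_back(u); t2.push_back(v); t3.push_back(nu[p]);
          ++p; ++q;
        }
      }
    }
  }
  IntegerMatrix out(t1.size(), 3);
  for (size_t i = 0; i < t1.size(); ++i) {
    out(i, 0) = t1[i]; out(i, 1) = t2[i]; out(i, 2) = t3[i];
  }
  return out;
}

// Count triangles by the number of negative edges they contain (0..3).
// Edge list with 1-based node ids; is_neg is 1 for N edges, 0 for P.
// Used on randomized draws where only class counts are needed.
// [[Rcpp::export]]
IntegerVector triangle_class_counts_cpp(int n_nodes, IntegerVector ea,
                                        IntegerVector eb,
                                        IntegerVector is_neg) {
  int m = ea.size();
  std::vector<std::vector<std::pair<int, int>>> fadj(n_nodes + 1);
  for (int i = 0; i < m; ++i) {
    int a = ea[i], b = eb[i];
    if (a > b) std::swap(a, b);
    fadj[a].push_back(std::make_pair(b, (int)is_neg[i]));
  }
  for (int u = 1; u <= n_nodes; ++u)
    std::sort(fadj[u].begin(), fadj[u].end());
  IntegerVector counts(4);
  for (int u = 1; u <= n_nodes; ++u) {
    const std::vector<std::pair<int, int>>& nu = fadj[u];
    for (size_t vi = 0; vi < nu.size(); ++vi) {
      int v = nu[vi].first, s_uv = nu[vi].second;
      const std::vector<std::pair<int, int>>& nv = fadj[v];
      size_t p = vi + 1, q = 0;
      while (p < nu.size() && q < nv.size()) {
        if (nu[p].first < nv[q].first) ++p;
        else if (nu[p].first > nv[q].first) ++q;
        else {
          int nneg = s_uv + nu[p].second + nv[q].second;
          counts[nneg] += 1;
          ++p; ++q;
        }
      }
    }
  }
  return counts; // index k = triangles with k negative edges
}
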