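#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Edge lists arrive 1-based (R convention) as an E x 2 integer matrix and are
// handled 0-based internally. All graphs are simple and undirected. The
// adjacency structure is a packed bitset (one row of ceil(n/64) words per
// node), which makes edge-existence checks O(1), triangle counting a
// popcount over row intersections, and breadth-first search bit-parallel.

struct BitGraph {
  int n, words;
  std::vector<uint64_t> adj;
  BitGraph(int n_) : n(n_), words((n_ + 63) / 64), adj((size_t)n_ * ((n_ + 63) / 64), 0) {}
  inline uint64_t* row(int v) { return adj.data() + (size_t)v * words; }
  inline const uint64_t* row(int v) const { return adj.data() + (size_t)v * words; }
  inline bool has(int a, int b) const { return (row(a)[b >> 6] >> (b & 63)) & 1ULL; }
  inline void set(int a, int b) {
    row(a)[b >> 6] |= 1ULL << (b & 63);
    row(b)[a >> 6] |= 1ULL << (a & 63);
  }
  inline void clear(int a, int b) {
    row(a)[b >> 6] &= ~(1ULL << (b & 63));
    row(b)[a >> 6] &= ~(1ULL << (a & 63));
  }
};

static BitGraph build_graph(const IntegerMatrix& edges, int n) {
  BitGraph g(n);
  for (int e = 0; e < edges.nrow(); ++e) g.set(edges(e, 0) - 1, edges(e, 1) - 1);
  return g;
}

// fast local generator (xoshiro256**), seeded from R's RNG so every call is
// reproducible under set.seed() while avoiding per-draw R RNG overhead
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ 0x9E3779B97F4A7C15ULL;
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline int below(int m) { return (int)(next() % (uint64_t)m); }
};

// Degree-preserving randomization by double edge swaps (Maslov-Sneppen).
// Performs `attempts` swap trials; trials creating self-loops or multi-edges
// are rejected. Reproducible under set.seed() on the R side.
// [[Rcpp::export]]
List cpp_rewire_degseq(IntegerMatrix edges, int n, double attempts) {
  int m = edges.nrow();
  IntegerMatrix out = clone(edges);
  double achieved = 0;
  if (m < 2) {
    return List::create(_["edges"] = out, _["achieved_swaps"] = 0.0,
                        _["attempted_swaps"] = attempts);
  }
  BitGraph g = build_graph(edges, n);
  Xoshiro rng;
  int* e1col = INTEGER(out);        // column-major: first column
  int* e2col = e1col + m;           // second column
  for (double it = 0; it < attempts; ++it) {
    int e1 = rng.below(m);
    int e2 = rng.below(m);
    if (e1 == e2) continue;
    int a = e1col[e1] - 1, b = e2col[e1] - 1;
    int c = e1col[e2] - 1, d = e2col[e2] - 1;
    // randomize which endpoints are exchanged so both swap orientations occur
    if (rng.next() & 1ULL) std::swap(c, d);
    // proposed replacement edges: (a,d) and (c,b)
    if (a == d || c == b) continue;
    if (g.has(a, d) || g.has(c, b)) continue;
    g.clear(a, b); g.clear(c, d);
    g.set(a, d); g.set(c, b);
    e1col[e1] = a + 1; e2col[e1] = d + 1;
    e1col[e2] = c + 1; e2col[e2] = b + 1;
    achieved += 1;
  }
  return List::create(_["edges"] = out, _["achieved_swaps"] = achieved,
                      _["attempted_swaps"] = attempts);
}

// Transitivity and characteristic path length of the largest connected
// component, in one pass: returns (transitivity, sum of finite shortest-path
// lengths over ordered pairs within the LCC, number of such pairs, LCC size).
// Transitivity is NaN when the LCC has no connected triples.
// [[Rcpp::export]]
NumericVector cpp_lcc_stats(IntegerMatrix edges, int n) {
  BitGraph g = build_graph(edges, n);
  int words = g.words;
  // connected components via bit-parallel BFS
  std::vector<int> comp(n, 0);
  std::vector<uint64_t> visited(words, 0), frontier(words), next(words);
  std::vector<int> comp_size;
  int label = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] != 0) continue;
    ++label;
    int size = 1;
    comp[s] = label;
    std::fill(frontier.begin(), frontier.end(), 0);
    frontier[s >> 6] |= 1ULL << (s & 63);
    visited[s >> 6] |= 1ULL << (s & 63);
    while (true) {
      std::fill(next.begin(), next.end(), 0);
      for (int w = 0; w < words; ++w) {
        uint64_t bits = frontier[w];
        while (bits) {
          int v = (w << 6) + __builtin_ctzll(bits);
          bits &= bits - 1;
          const uint64_t* rv = g.row(v);
          for (int u = 0; u < words; ++u) next[u] |= rv[u];
        }
      }
      int found = 0;
      for (int w = 0; w < words; ++w) {
        next[w] &= ~visited[w];
        visited[w] |= next[w];
        uint64_t bits = next[w];
        while (bits) {
          int v = (w << 6) + __builtin_ctzll(bits);
          bits &= bits - 1;
          comp[v] = label;
          ++found;
        }
      }
      if (found == 0) break;
      size += found;
      frontier.swap(next);
    }
    comp_size.push_back(size);
  }
  int main_label = 1;
  for (size_t i = 1; i < comp_size.size(); ++i) {
    if (comp_size[i] > comp_size[main_label - 1]) main_label = (int)i + 1;
  }
  double lcc_size = comp_size.empty() ? 0 : comp_size[main_label - 1];

  // membership mask of the largest component
  std::vector<uint64_t> in_lcc(words, 0);
  for (int v = 0; v < n; ++v) {
    if (comp[v] == main_label) in_lcc[v >> 6] |= 1ULL << (v & 63);
  }

  // transitivity over the LCC (every edge incident to an LCC node lies
  // inside it, so filtering by one endpoint suffices)
  double triples = 0.0, closed = 0.0;
  for (int v = 0; v < n; ++v) {
    if (comp[v] != main_label) continue;
    double k = 0;
    const uint64_t* r = g.row(v);
    for (int w = 0; w < words; ++w) k += __builtin_popcountll(r[w]);
    triples += k * (k - 1.0) / 2.0;
  }
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0) - 1;
    if (comp[a] != main_label) continue;
    const uint64_t* ra = g.row(a);
    const uint64_t* rb = g.row(edges(e, 1) - 1);
    for (int w = 0; w < words; ++w) closed += __builtin_popcountll(ra[w] & rb[w]);
  }
  double transitivity = (triples == 0.0) ? R_NaN : closed / triples;

  // path lengths within the LCC: seed `visited` with the complement mask so
  // breadth-first search never leaves the component
  double total = 0.0, reached = 0.0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] != main_label) continue;
    for (int w = 0; w < words; ++w) visited[w] = ~in_lcc[w];
    std::fill(frontier.begin(), frontier.end(), 0);
    visited[s >> 6] |= 1ULL << (s & 63);
    frontier[s >> 6] |= 1ULL << (s & 63);
    double level = 0;
    while (true) {
      std::fill(next.begin(), next.end(), 0);
      for (int w = 0; w < words; ++w) {
        uint64_t bits = frontier[w];
        while (bits) {
          int v = (w << 6) + __builtin_ctzll(bits);
          bits &= bits - 1;
          const uint64_t* rv = g.row(v);
          for (int u = 0; u < words; ++u) next[u] |= rv[u];
        }
      }
      ++level;
      double found = 0;
      for (int w = 0; w < words; ++w) {
        next[w] &= ~visited[w];
        visited[w] |= next[w];
        found += __builtin_popcountll(next[w]);
      }
      if (found == 0) break;
      total += level * found;
      reached += found;
      frontier.swap(next);
    }
  }
  return NumericVector::create(transitivity, total, reached, lcc_size);
}

// Global transitivity: 3 * triangles / connected triples.
// Returns NaN when the graph has no connected triples.
// [[Rcpp::export]]
double cpp_transitivity(IntegerMatrix edges, int n) {
  BitGraph g = build_graph(edges, n);
  double triples = 0.0;
  for (int v = 0; v < n; ++v) {
    double k = 0;
    const uint64_t* r = g.row(v);
    for (int w = 0; w < g.words; ++w) k += __builtin_popcountll(r[w]);
    triples += k * (k - 1.0) / 2.0;
  }
  if (triples == 0.0) return R_NaN;
  // each triangle is counted once per incident edge, i.e. 3 times in total
  double closed = 0.0;
  for (int e = 0; e < edges.nrow(); ++e) {
    const uint64_t* ra = g.row(edges(e, 0) - 1);
    const uint64_t* rb = g.row(edges(e, 1) - 1);
    for (int w = 0; w < g.words; ++w) closed += __builtin_popcountll(ra[w] & rb[w]);
  }
  return closed / triples;
}

// All-pairs bit-parallel BFS. Returns the sum of finite shortest-path lengths
// over ordered pairs, the number of reachable ordered pairs, and the number
// of unreachable ordered pairs (self-pairs excluded throughout).
// [[Rcpp::export]]
NumericVector cpp_path_length(IntegerMatrix edges, int n) {
  BitGraph g = build_graph(edges, n);
  int words = g.words;
  std::vector<uint64_t> visited(words), frontier(words), next(words);
  double total = 0.0, reached = 0.0;
  for (int s = 0; s < n; ++s) {
    std::fill(visited.begin(), visited.end(), 0);
    std::fill(frontier.begin(), frontier.end(), 0);
    visited[s >> 6] |= 1ULL << (s & 63);
    frontier[s >> 6] |= 1ULL << (s & 63);
    double level = 0;
    while (true) {
      std::fill(next.begin(), next.end(), 0);
      for (int w = 0; w < words; ++w) {
        uint64_t bits = frontier[w];
        while (bits) {
          int v = (w << 6) + __builtin_ctzll(bits);
          bits &= bits - 1;
          const uint64_t* rv = g.row(v);
          for (int u = 0; u < words; ++u) next[u] |= rv[u];
        }
      }
      ++level;
      double found = 0;
      for (int w = 0; w < words; ++w) {
        next[w] &= ~visited[w];
        visited[w] |= next[w];
        found += __builtin_popcountll(next[w]);
      }
      if (found == 0) break;
      total += level * found;
      reached += found;
      frontier.swap(next);
    }
  }
  double unreachable = (double)n * (n - 1.0) - reached;
  return NumericVector::create(total, reached, unreachable);
}

// Connected-component labels (1-based, by discovery order).
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerMatrix edges, int n) {
  BitGraph g = build_graph(edges, n);
  int words = g.words;
  IntegerVector comp(n, 0);
  std::vector<uint64_t> visited(words), frontier(words), next(words);
  int label = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] != 0) continue;
    ++label;
    std::fill(frontier.begin(), frontier.end(), 0);
    frontier[s >> 6] |= 1ULL << (s & 63);
    visited[s >> 6] |= 1ULL << (s & 63);
    comp[s] = label;
    while (true) {
      std::fill(next.begin(), next.end(), 0);
      for (int w = 0; w < words; ++w) {
        uint64_t bits = frontier[w];
        while (bits) {
          int v = (w << 6) + __builtin_ctzll(bits);
          bits &= bits - 1;
          const uint64_t* rv = g.row(v);
          for (int u = 0; u < words; ++u) next[u] |= rv[u];
        }
      }
      double found = 0;
      for (int w = 0; w < words; ++w) {
        next[w] &= ~visited[w];
        visited[w] |= next[w];
        uint64_t bits = next[w];
        found += __builtin_popcountll(bits);
        while (bits) {
          int v = (w << 6) + __builtin_ctzll(bits);
          bits &= bits - 1;
          comp[v] = label;
        }
      }
      if (found == 0) break;
      frontier.swap(next);
    }
  }
  return comp;
}
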