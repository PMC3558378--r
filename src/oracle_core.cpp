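// Brute-force reference machinery used by the test oracles.
//
// All routines work on small graphs (<= 63 vertices) represented as 0/1
// adjacency matrices, with vertex sets held in 64-bit masks.  They are
// intentionally naive and independent of the separator-based pipeline
// implemented in R: chordality is decided by simplicial elimination (not
// MCS), minimal separators by definition-level scans, and proper
// triangulations by branching over legal chords of chordless cycles.

#include <Rcpp.h>
#include <cstdint>
#include <set>
#include <vector>
#include <algorithm>

using namespace Rcpp;
typedef uint64_t mask_t;

static std::vector<mask_t> nbr_masks(const IntegerMatrix& adj) {
  int n = adj.nrow();
  if (n > 63) stop("oracle routines support at most 63 vertices");
  std::vector<mask_t> nbr(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j)) nbr[i] |= (mask_t(1) << j);
  return nbr;
}

static mask_t full_mask(int n) {
  return n == 63 ? ~mask_t(0) : ((mask_t(1) << n) - 1);
}

// connected components of the graph induced on `alive`
static std::vector<mask_t> components_of(const std::vector<mask_t>& nbr,
                                         mask_t alive) {
  std::vector<mask_t> comps;
  mask_t todo = alive;
  while (todo) {
    int v = __builtin_ctzll(todo);
    mask_t comp = mask_t(1) << v, frontier = comp;
    while (frontier) {
      mask_t nxt = 0;
      mask_t f = frontier;
      while (f) {
        int u = __builtin_ctzll(f);
        f &= f - 1;
        nxt |= nbr[u];
      }
      nxt &= alive & ~comp;
      comp |= nxt;
      frontier = nxt;
    }
    comps.push_back(comp);
    todo &= ~comp;
  }
  return comps;
}

static mask_t neighborhood_of(const std::vector<mask_t>& nbr, mask_t set) {
  mask_t nb = 0, s = set;
  while (s) {
    int v = __builtin_ctzll(s);
    s &= s - 1;
    nb |= nbr[v];
  }
  return nb & ~set;
}

// S is a minimal separator iff >= 2 components of G - S are full (N(C) == S)
static bool is_min_separator(const std::vector<mask_t>& nbr, int n, mask_t S) {
  mask_t alive = full_mask(n) & ~S;
  if (!alive) return false;
  std::vector<mask_t> comps = components_of(nbr, alive);
  int nfull = 0;
  for (mask_t c : comps)
    if (neighborhood_of(nbr, c) == S && ++nfull >= 2) return true;
  return false;
}

static IntegerVector mask_to_vertices(mask_t m) {
  IntegerVector out;
  while (m) {
    int v = __builtin_ctzll(m);
    m &= m - 1;
    out.push_back(v + 1);  // 1-based for R
  }
  return out;
}

// [[Rcpp::export]]
List cpp_min_seps_subsets(IntegerMatrix adj) {
  int n = adj.nrow();
  if (n > 22) stop("subset scan limited to 22 vertices");
  std::vector<mask_t> nbr = nbr_masks(adj);
  mask_t all = full_mask(n);
  List out;
  for (mask_t S = 0; S < all; ++S)  // S == all removes everything
    if (is_min_separator(nbr, n, S)) out.push_back(mask_to_vertices(S));
  return out;
}

// Berry-Bordat-Cogis style enumeration: seed with N(C) for components C of
// G - N[v], then expand each separator S through G - (S | N(x)), x in S.
// Every candidate is re-certified by the two-full-components test before
// being kept, so the output is sound even independent of the BBC theorem.
// [[Rcpp::export]]
List cpp_min_seps_close(IntegerMatrix adj) {
  int n = adj.nrow();
  std::vector<mask_t> nbr = nbr_masks(adj);
  mask_t all = full_mask(n);
  std::set<mask_t> found;
  std::vector<mask_t> queue;
  if (components_of(nbr, all).size() >= 2) found.insert(0);  // empty separator
  for (int v = 0; v < n; ++v) {
    mask_t closed = nbr[v] | (mask_t(1) << v);
    for (mask_t c : components_of(nbr, all & ~closed)) {
      mask_t S = neighborhood_of(nbr, c);
      if (S && !found.count(S) && is_min_separator(nbr, n, S)) {
        found.insert(S);
        queue.push_back(S);
      }
    }
  }
  while (!queue.empty()) {
    mask_t S = queue.back();
    queue.pop_back();
    mask_t s = S;
    while (s) {
      int x = __builtin_ctzll(s);
      s &= s - 1;
      mask_t rem = S | nbr[x] | (mask_t(1) << x);
      for (mask_t c : components_of(nbr, all & ~rem)) {
        mask_t S2 = neighborhood_of(nbr, c);
        if (S2 && !found.count(S2) && is_min_separator(nbr, n, S2)) {
          found.insert(S2);
          queue.push_back(S2);
        }
      }
    }
  }
  List out;
  for (mask_t S : found) out.push_back(mask_to_vertices(S));
  return out;
}

// chordality by repeated deletion of simplicial vertices
static bool chordal_elim(std::vector<mask_t> nbr, int n) {
  mask_t alive = full_mask(n);
  int remaining = n;
  while (remaining > 0) {
    bool progress = false;
    mask_t a = alive;
    while (a) {
      int v = __builtin_ctzll(a);
      a &= a - 1;
      mask_t nv = nbr[v] & alive;
      bool simplicial = true;
      mask_t t = nv;
      while (t && simplicial) {
        int u = __builtin_ctzll(t);
        t &= t - 1;
        if ((nv & ~(nbr[u] | (mask_t(1) << u))) != 0) simplicial = false;
      }
      if (simplicial) {
        alive &= ~(mask_t(1) << v);
        --remaining;
        progress = true;
      }
    }
    if (!progress) return false;
  }
  return true;
}

// [[Rcpp::export]]
bool cpp_is_chordal_elim(IntegerMatrix adj) {
  return chordal_elim(nbr_masks(adj), adj.nrow());
}

// Find one chordless cycle of length >= 4, or empty vector if chordal.
// For each v and non-adjacent u,w in N(v): a shortest u-w path avoiding
// N[v] \ {u,w} closes a chordless cycle through v.
static std::vector<int> find_chordless_cycle(const std::vector<mask_t>& nbr,
                                             int n) {
  mask_t all = full_mask(n);
  for (int v = 0; v < n; ++v) {
    mask_t nv = nbr[v];
    mask_t s1 = nv;
    while (s1) {
      int u = __builtin_ctzll(s1);
      s1 &= s1 - 1;
      mask_t s2 = s1;  // w > u
      while (s2) {
        int w = __builtin_ctzll(s2);
        s2 &= s2 - 1;
        if (nbr[u] & (mask_t(1) << w)) continue;  // adjacent: triangle
        mask_t allowed = all & ~(nv | (mask_t(1) << v));
        allowed |= (mask_t(1) << u) | (mask_t(1) << w);
        // BFS shortest path u -> w inside allowed
        std::vector<int> parent(n, -2);
        std::vector<int> bfs;
        bfs.push_back(u);
        parent[u] = -1;
        bool reached = false;
        for (size_t qi = 0; qi < bfs.size() && !reached; ++qi) {
          int x = bfs[qi];
          mask_t nx = nbr[x] & allowed;
          while (nx) {
            int y = __builtin_ctzll(nx);
            nx &= nx - 1;
            if (parent[y] == -2) {
              parent[y] = x;
              if (y == w) { reached = true; break; }
              bfs.push_back(y);
            }
          }
        }
        if (reached) {
          std::vector<int> cyc;
          cyc.push_back(v);
          std::vector<int> path;
          for (int x = w; x != -1; x = parent[x]) path.push_back(x);
          // path is w..u; want v,u,...,w
          for (auto it = path.rbegin(); it != path.rend(); ++it)
            cyc.push_back(*it);
          return cyc;  // cycle v-u-...-w-v, chordless, length >= 4
        }
      }
    }
  }
  return std::vector<int>();
}

// [[Rcpp::export]]
IntegerVector cpp_find_chordless_cycle(IntegerMatrix adj) {
  std::vector<int> c = find_chordless_cycle(nbr_masks(adj), adj.nrow());
  IntegerVector out(c.size());
  for (size_t i = 0; i < c.size(); ++i) out[i] = c[i] + 1;
  return out;
}

struct TriSearch {
  int n;
  std::vector<int> colors;
  std::set<std::vector<int>> seen;        // fill sets already explored
  std::set<std::vector<int>> chordal_fill;  // fill sets reaching chordality
  bool decide_only, found;
  long nodes, node_limit;
};

static std::vector<int> fills_key(const std::vector<std::pair<int, int>>& f) {
  std::vector<int> key;
  key.reserve(f.size());
  for (auto& e : f) key.push_back(e.first * 64 + e.second);
  std::sort(key.begin(), key.end());
  return key;
}

static void tri_recurse(TriSearch& ts, std::vector<mask_t>& nbr,
                        std::vector<std::pair<int, int>>& fills) {
  if (ts.decide_only && ts.found) return;
  if (++ts.nodes > ts.node_limit)
    stop("triangulation search exceeded its size limit");
  std::vector<int> key = fills_key(fills);
  if (!ts.seen.insert(key).second) return;
  std::vector<int> cyc = find_chordless_cycle(nbr, ts.n);
  if (cyc.empty()) {
    ts.chordal_fill.insert(key);
    ts.found = true;
    return;
  }
  int L = cyc.size();
  for (int i = 0; i < L; ++i) {
    for (int j = i + 2; j < L; ++j) {
      if (i == 0 && j == L - 1) continue;  // consecutive on the cycle
      int u = cyc[i], w = cyc[j];
      if (ts.colors[u] == ts.colors[w]) continue;       // illegal chord
      if (nbr[u] & (mask_t(1) << w)) continue;          // already an edge
      int a = std::min(u, w), b = std::max(u, w);
      nbr[a] |= (mask_t(1) << b);
      nbr[b] |= (mask_t(1) << a);
      fills.push_back(std::make_pair(a, b));
      tri_recurse(ts, nbr, fills);
      fills.pop_back();
      nbr[a] &= ~(mask_t(1) << b);
      nbr[b] &= ~(mask_t(1) << a);
      if (ts.decide_only && ts.found) return;
    }
  }
}

// Enumerate fill sets (as k x 2 matrices, 1-based) that make the colored
// graph chordal using only legal chords, by branching on chordless cycles.
// When decide_only, stops at the first success and returns at most one.
// [[Rcpp::export]]
List cpp_proper_fills(IntegerMatrix adj, IntegerVector colors,
                      bool decide_only, double node_limit) {
  TriSearch ts;
  ts.n = adj.nrow();
  ts.colors = as<std::vector<int>>(colors);
  ts.decide_only = decide_only;
  ts.found = false;
  ts.nodes = 0;
  ts.node_limit = (long)node_limit;
  std::vector<mask_t> nbr = nbr_masks(adj);
  std::vector<std::pair<int, int>> fills;
  tri_recurse(ts, nbr, fills);
  List out;
  for (const std::vector<int>& key : ts.chordal_fill) {
    IntegerMatrix ed(key.size(), 2);
    for (size_t i = 0; i < key.size(); ++i) {
      ed(i, 0) = key[i] / 64 + 1;
      ed(i, 1) = key[i] % 64 + 1;
    }
    out.push_back(ed);
  }
  return out;
}

// [[Rcpp::export]]
bool cpp_is_minimal_fill(IntegerMatrix adj, IntegerMatrix fill) {
  // adj must already contain the fill edges; removing any single one of
  // them must break chordality for the triangulation to be minimal
  int n = adj.nrow();
  std::vector<mask_t> nbr = nbr_masks(adj);
  if (!chordal_elim(nbr, n)) return false;
  for (int k = 0; k < fill.nrow(); ++k) {
    int a = fill(k, 0) - 1, b = fill(k, 1) - 1;
    std::vector<mask_t> nb2 = nbr;
    nb2[a] &= ~(mask_t(1) << b);
    nb2[b] &= ~(mask_t(1) << a);
    if (chordal_elim(nb2, n)) return false;
  }
  return true;
}
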