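// Vietoris-Rips 1-persistence over Z/p.
//
// Pairs are computed from the coboundary (anti-transposed boundary)
// matrix: persistence pairs of the boundary reduction equal those of the
// coboundary reduction with rows and columns taken in reverse filtration
// order.  For dimension-1 pairs this means one column per edge (entries =
// cofacet triangles) instead of one column per triangle, which is far
// cheaper on dense filtrations; triangles are never materialized globally.
//
// Simplices enter at: vertices 0, edges their length, triangles their
// longest edge.  Deterministic total order: filtration value, then
// dimension, then lexicographic vertex tuple.  Tree edges (those merging
// connected components, found by union-find) pair with vertices and their
// coboundary columns provably reduce to zero, so they are skipped.
// Positive edges whose column reduces to zero create 1-cycles that survive
// past max_scale and are reported censored there.
//
// Columns claimed with an uncontested pivot (the common case) are recorded
// as a bare edge reference -- no sort, no copy; a sorted explicit column is
// materialized only the first time a column is needed as a reducer.
// Contested columns are reduced through a lazy min-heap whose duplicate
// entries accumulate on extraction.  The default field Z/2 runs a
// specialized path with 16-byte heap entries and parity accumulation; odd
// primes carry explicit coefficients.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Edge {
  double len;
  int i, j;
};

inline bool edge_less(const Edge& a, const Edge& b) {
  if (a.len != b.len) return a.len < b.len;
  if (a.i != b.i) return a.i < b.i;
  return a.j < b.j;
}

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int v = 0; v < n; ++v) parent[v] = v;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[b] = a;
    return true;
  }
};

// a triangle (i<j<k) as a column entry: filtration value and packed vertex
// tuple (lexicographic order == numeric order on the packed key); valid
// for n < 2^21
inline int64_t pack3(int i, int j, int k) {
  return ((int64_t)i << 42) | ((int64_t)j << 21) | (int64_t)k;
}

inline int mod_inverse(int a, int p) {
  int result = 1, base = a % p, e = p - 2;
  while (e > 0) {
    if (e & 1) result = (int)((int64_t)result * base % p);
    base = (int)((int64_t)base * base % p);
    e >>= 1;
  }
  return result;
}

// --- coefficient policies ---------------------------------------------

// Z/2: coefficients are implicit (always 1); duplicates cancel in pairs
struct PolicyZ2 {
  struct Entry {
    double val;
    int64_t key;
  };
  int p;
  explicit PolicyZ2(int) : p(2) {}
  static Entry make(double val, int64_t key, int) {
    Entry e; e.val = val; e.key = key; return e;
  }
  // accumulate duplicates of `first` popped off the heap; true if the
  // combined coefficient is nonzero
  template <class Heap>
  bool accumulate(Heap& heap, Entry& first) const {
    int count = 1;
    while (!heap.empty() && heap.top().key == first.key) {
      ++count;
      heap.pop();
    }
    return (count & 1) != 0;
  }
  // scale factor cancelling `piv` against a reducer with pivot coef
  int cancel_factor(const Entry&, int) const { return 1; }
  static Entry scaled(const Entry& e, int, bool& keep) {
    keep = true;
    return e;
  }
  static int coef_of(const Entry&) { return 1; }
};

// odd prime: explicit coefficients in 1..p-1
struct PolicyZp {
  struct Entry {
    double val;
    int64_t key;
    int coef;
  };
  int p;
  explicit PolicyZp(int p_) : p(p_) {}
  Entry make(double val, int64_t key, int coef) const {
    Entry e; e.val = val; e.key = key; e.coef = coef % p;
    return e;
  }
  template <class Heap>
  bool accumulate(Heap& heap, Entry& first) const {
    int64_t coef = first.coef;
    while (!heap.empty() && heap.top().key == first.key) {
      coef += heap.top().coef;
      heap.pop();
    }
    first.coef = (int)(coef % p);
    return first.coef != 0;
  }
  int cancel_factor(const Entry& piv, int red_piv_coef) const {
    return (int)((int64_t)(p - piv.coef) * mod_inverse(red_piv_coef, p) % p);
  }
  Entry scaled(const Entry& e, int c, bool& keep) const {
    Entry out = e;
    out.coef = (int)((int64_t)e.coef * c % p);
    keep = out.coef != 0;
    return out;
  }
  static int coef_of(const Entry& e) { return e.coef; }
};

// --- templated reduction ----------------------------------------------

template <class Policy>
List reduce_h1(const std::vector<double>& D, int n,
               const std::vector<Edge>& edges,
               const std::vector<bool>& positive,
               double max_scale, Policy pol) {
  typedef typename Policy::Entry Entry;
  struct EntryLess {
    bool operator()(const Entry& a, const Entry& b) const {
      if (a.val != b.val) return a.val < b.val;
      return a.key < b.key;
    }
  };
  struct EntryAfter {
    bool operator()(const Entry& a, const Entry& b) const {
      if (a.val != b.val) return a.val > b.val;
      return a.key > b.key;
    }
  };
  typedef std::vector<Entry> Column;
  typedef std::priority_queue<Entry, std::vector<Entry>, EntryAfter> Heap;
  struct Stored {
    int src_edge;
    bool have;
    int piv_coef;
    Column column;
  };

  const int ne = (int)edges.size();
  const int p = pol.p;

  // cofacet enumeration for one edge (unsorted)
  auto assemble = [&](int eid, Column& out) {
    const int i = edges[eid].i, j = edges[eid].j;
    const double lij = edges[eid].len;
    const double* Di = &D[(size_t)i * n];
    const double* Dj = &D[(size_t)j * n];
    for (int k = 0; k < n; ++k) {
      if (k == i || k == j) continue;
      double dik = Di[k], djk = Dj[k];
      if (dik > max_scale || djk > max_scale) continue;
      double val = std::max(lij, std::max(dik, djk));
      // coefficient of edge in d(a<b<c): (b,c) +1, (a,c) -1, (a,b) +1
      if (k < i) out.push_back(pol.make(val, pack3(k, i, j), 1));
      else if (k < j) out.push_back(pol.make(val, pack3(i, k, j), p - 1));
      else out.push_back(pol.make(val, pack3(i, j, k), 1));
    }
  };

  std::unordered_map<int64_t, int> pivot_owner; // triangle key -> column id
  pivot_owner.reserve(2 * (size_t)ne);
  std::vector<Stored> stored;
  std::vector<double> pair_birth, pair_death, cens_birth;
  Column col;

  auto materialize = [&](Stored& s) -> const Column& {
    if (!s.have) {
      s.column.clear();
      assemble(s.src_edge, s.column);
      std::sort(s.column.begin(), s.column.end(), EntryLess());
      s.piv_coef = Policy::coef_of(s.column.front());
      s.have = true;
    }
    return s.column;
  };

  // pop the minimal entry with nonzero accumulated coefficient
  auto get_pivot = [&](Heap& heap, Entry& out) -> bool {
    while (!heap.empty()) {
      Entry top = heap.top();
      heap.pop();
      if (pol.accumulate(heap, top)) { out = top; return true; }
    }
    return false;
  };

  // process edge columns in reverse filtration order (anti-transpose)
  for (int e = ne - 1; e >= 0; --e) {
    if (!positive[e]) continue; // tree edge: column reduces to zero
    const double lij = edges[e].len;

    col.clear();
    assemble(e, col);
    if (col.empty()) {
      if (lij < max_scale) cens_birth.push_back(lij);
      continue;
    }

    // fast path: uncontested pivot needs no sort and no column copy
    size_t imin = 0;
    for (size_t q = 1; q < col.size(); ++q)
      if (EntryLess()(col[q], col[imin])) imin = q;
    {
      const Entry& piv = col[imin];
      typename std::unordered_map<int64_t, int>::iterator it =
          pivot_owner.find(piv.key);
      if (it == pivot_owner.end()) {
        pivot_owner[piv.key] = (int)stored.size();
        Stored s; s.src_edge = e; s.have = false;
        s.piv_coef = Policy::coef_of(piv);
        stored.push_back(s);
        if (lij < piv.val) {
          pair_birth.push_back(lij);
          pair_death.push_back(piv.val);
        }
        continue;
      }
    }

    // contested: lazy-heap reduction (coefficients accumulate on pop)
    Heap heap(EntryAfter(), col);
    Entry piv;
    bool paired = false;
    while (get_pivot(heap, piv)) {
      typename std::unordered_map<int64_t, int>::iterator it =
          pivot_owner.find(piv.key);
      if (it == pivot_owner.end()) {
        pivot_owner[piv.key] = (int)stored.size();
        Stored s; s.src_edge = e; s.have = true;
        s.piv_coef = Policy::coef_of(piv);
        s.column.push_back(piv);
        Entry rest;
        while (get_pivot(heap, rest)) s.column.push_back(rest);
        stored.push_back(s);
        if (lij < piv.val) {
          pair_birth.push_back(lij);
          pair_death.push_back(piv.val);
        }
        paired = true;
        break;
      }
      const Column& red = materialize(stored[it->second]);
      int c = pol.cancel_factor(piv, stored[it->second].piv_coef);
      // the reducer's pivot (front) cancels the extracted pivot exactly:
      // add the tail only, and drop the extracted pivot
      for (size_t q = 1; q < red.size(); ++q) {
        bool keep;
        Entry add = pol.scaled(red[q], c, keep);
        if (keep) heap.push(add);
      }
    }
    if (!paired && lij < max_scale) cens_birth.push_back(lij);
  }

  const size_t np = pair_birth.size(), nc = cens_birth.size();
  NumericVector birth(np + nc), death(np + nc);
  LogicalVector censored(np + nc);
  for (size_t q = 0; q < np; ++q) {
    birth[q] = pair_birth[q]; death[q] = pair_death[q]; censored[q] = false;
  }
  for (size_t q = 0; q < nc; ++q) {
    birth[np + q] = cens_birth[q]; death[np + q] = max_scale;
    censored[np + q] = true;
  }
  return List::create(_["birth"] = birth, _["death"] = death,
                      _["censored"] = censored);
}

} // namespace

// [[Rcpp::export(name = ".rips_h1_cpp")]]
List rips_h1_cpp(NumericMatrix dm, double max_scale, int field_char) {
  const int n = dm.nrow();
  if (dm.ncol() != n) stop("distance matrix must be square");
  if (n >= (1 << 21)) stop("too many points");

  std::vector<double> D((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) D[(size_t)i * n + j] = dm(i, j);

  std::vector<Edge> edges;
  edges.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dij = D[(size_t)i * n + j];
      if (dij < 0) stop("negative distance");
      if (dij <= max_scale) {
        Edge e; e.len = dij; e.i = i; e.j = j;
        edges.push_back(e);
      }
    }
  }
  std::sort(edges.begin(), edges.end(), edge_less);

  std::vector<bool> positive(edges.size(), false);
  {
    UnionFind uf(n);
    for (size_t e = 0; e < edges.size(); ++e)
      if (!uf.unite(edges[e].i, edges[e].j)) positive[e] = true;
  }

  if (field_char == 2)
    return reduce_h1(D, n, edges, positive, max_scale, PolicyZ2(2));
  return reduce_h1(D, n, edges, positive, max_scale, PolicyZp(field_char));
}
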