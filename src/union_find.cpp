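#include <Rcpp.h>
using namespace Rcpp;

// Disjoint-set forest over 0-based node indices with path halving.
// Union keeps the smaller root index, so the root of every component is its
// smallest member index; with nodes pre-sorted lexicographically this makes
// canonical (smallest-id) cluster labels fall out of find() directly.

static inline int uf_find_(IntegerVector &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export]]
IntegerVector uf_init(int n) {
  IntegerVector p(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  return p;
}

// Unions edges (ia[k], ib[k]) into `parent` in place. `parent` must be a
// vector freshly created by uf_init() and owned by the caller (in-place
// mutation is what lets the streaming pass keep O(nodes) state).
// [[Rcpp::export]]
void uf_union_batch(IntegerVector parent, IntegerVector ia, IntegerVector ib) {
  R_xlen_t m = ia.size();
  for (R_xlen_t k = 0; k < m; ++k) {
    int ra = uf_find_(parent, ia[k] - 1);
    int rb = uf_find_(parent, ib[k] - 1);
    if (ra == rb) continue;
    if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
  }
}

// Fully resolved component root (1-based) for every node.
// [[Rcpp::export]]
IntegerVector uf_roots(IntegerVector parent) {
  int n = parent.size();
  IntegerVector r(n);
  for (int i = 0; i < n; ++i) r[i] = uf_find_(parent, i) + 1;
  return r;
}
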