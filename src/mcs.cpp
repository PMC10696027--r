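#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Exact maximum common connected induced subgraph (MCS) search between
// two molecular graphs, counted in heavy atoms.
//
// A common subgraph is a partial injective atom mapping f that preserves
// adjacency in both directions: for every mapped pair, bond(u,v) in A has
// the same order as bond(f(u),f(v)) in B, where "no bond" is an order of
// its own. The mapped subgraph must be connected. Atom compatibility is
// element equality; bond orders match exactly with aromatic treated as
// its own order. Induced matching guarantees Tanimoto = 1 iff the two
// heavy-atom graphs are isomorphic.
//
// McGregor-style branch and bound: mappings are grown only through shared
// bonds, so connectivity holds by construction; every connected common
// subgraph has a spanning tree and is therefore reachable. Duplicate work
// is limited by (i) rooting each search at the minimum A-atom index of the
// subgraph and (ii) the include/exclude branching rule: once a candidate
// pair has been fully explored at a search node, it is forbidden in the
// remaining branches of that node.

namespace {

struct Graph {
  int n;
  // adjacency: for atom i, list of (neighbour, bond order code)
  std::vector<std::vector<std::pair<int, int> > > adj;
  std::vector<int> elem;
  std::vector<int> order; // n*n bond-order matrix, 0 = no bond
  int bond(int i, int j) const { return order[(size_t)i * n + j]; }
};

struct Search {
  const Graph *A, *B;
  std::vector<int> mapAB;     // A index -> B index or -1
  std::vector<int> mapBA;     // B index -> A index or -1
  std::vector<char> forbidden; // a * nB + b -> excluded pair at some ancestor
  int root;                   // minimum A index allowed in this component
  int best;
  long long expansions;
  long long cap;
  bool capped;
};

void extend(Search &s, int cur) {
  if (s.capped) return;
  if (++s.expansions > s.cap) { s.capped = true; return; }
  if (cur > s.best) s.best = cur;

  // collect frontier candidate pairs (a, b): a unmapped with a > root and
  // adjacent to a mapped atom a' via a bond whose order also links
  // f(a') to unmapped b in B
  std::vector<std::pair<int, int> > cand;
  const Graph &A = *s.A, &B = *s.B;
  for (int ap = 0; ap < A.n; ++ap) {
    if (s.mapAB[ap] < 0) continue;
    int bp = s.mapAB[ap];
    for (size_t k = 0; k < A.adj[ap].size(); ++k) {
      int a = A.adj[ap][k].first, oa = A.adj[ap][k].second;
      if (a <= s.root || s.mapAB[a] >= 0) continue;
      for (size_t l = 0; l < B.adj[bp].size(); ++l) {
        int b = B.adj[bp][l].first, ob = B.adj[bp][l].second;
        if (s.mapBA[b] >= 0 || ob != oa) continue;
        if (A.elem[a] != B.elem[b]) continue;
        if (s.forbidden[(size_t)a * B.n + b]) continue;
        // induced: (a, b) must agree with every mapped pair on bond order
        bool compatible = true;
        for (int a2 = 0; a2 < A.n && compatible; ++a2) {
          if (s.mapAB[a2] < 0) continue;
          if (A.bond(a, a2) != B.bond(b, s.mapAB[a2])) compatible = false;
        }
        if (!compatible) continue;
        bool seen = false;
        for (size_t q = 0; q < cand.size(); ++q)
          if (cand[q].first == a && cand[q].second == b) { seen = true; break; }
        if (!seen) cand.push_back(std::make_pair(a, b));
      }
    }
  }
  if (cand.empty()) return;

  // bound: every further atom consumes one unmapped atom on each side
  int freeA = 0, freeB = 0;
  for (int a = s.root + 1; a < A.n; ++a) if (s.mapAB[a] < 0) ++freeA;
  for (int b = 0; b < B.n; ++b) if (s.mapBA[b] < 0) ++freeB;
  if (cur + std::min(freeA, freeB) <= s.best) return;

  std::vector<char> locally_forbidden(cand.size(), 0);
  for (size_t i = 0; i < cand.size(); ++i) {
    int a = cand[i].first, b = cand[i].second;
    s.mapAB[a] = b; s.mapBA[b] = a;
    extend(s, cur + 1);
    s.mapAB[a] = -1; s.mapBA[b] = -1;
    if (s.capped) { /* fallthrough to restore */ }
    s.forbidden[(size_t)a * B.n + b] = 1;
    locally_forbidden[i] = 1;
    if (s.capped) break;
  }
  for (size_t i = 0; i < cand.size(); ++i)
    if (locally_forbidden[i])
      s.forbidden[(size_t)cand[i].first * B.n + cand[i].second] = 0;
}

Graph build_graph(int n, IntegerVector elem, IntegerMatrix bonds) {
  Graph g;
  g.n = n;
  g.elem.assign(elem.begin(), elem.end());
  g.adj.assign(n, std::vector<std::pair<int, int> >());
  g.order.assign((size_t)n * n, 0);
  for (int r = 0; r < bonds.nrow(); ++r) {
    int i = bonds(r, 0) - 1, j = bonds(r, 1) - 1, o = bonds(r, 2);
    g.adj[i].push_back(std::make_pair(j, o));
    g.adj[j].push_back(std::make_pair(i, o));
    g.order[(size_t)i * n + j] = o;
    g.order[(size_t)j * n + i] = o;
  }
  return g;
}

} // namespace

//' @useDynLib csntox, .registration = TRUE
//' @importFrom Rcpp evalCpp
// [[Rcpp::export]]
List mcs_size_cpp(IntegerVector elem_a, IntegerMatrix bonds_a,
                  IntegerVector elem_b, IntegerMatrix bonds_b,
                  double max_expansions) {
  Graph A = build_graph(elem_a.size(), elem_a, bonds_a);
  Graph B = build_graph(elem_b.size(), elem_b, bonds_b);

  Search s;
  s.A = &A; s.B = &B;
  s.mapAB.assign(A.n, -1);
  s.mapBA.assign(B.n, -1);
  s.forbidden.assign((size_t)A.n * (size_t)B.n, 0);
  s.best = 0;
  s.expansions = 0;
  s.cap = (long long)max_expansions;
  s.capped = false;

  int maxpos = std::min(A.n, B.n);
  for (int a0 = 0; a0 < A.n && !s.capped; ++a0) {
    if (s.best >= maxpos) break;
    // subgraphs whose minimum A index is a0 can use at most A.n - a0 atoms
    if (A.n - a0 <= s.best) break;
    for (int b0 = 0; b0 < B.n && !s.capped; ++b0) {
      if (A.elem[a0] != B.elem[b0]) continue;
      s.root = a0;
      s.mapAB[a0] = b0; s.mapBA[b0] = a0;
      extend(s, 1);
      s.mapAB[a0] = -1; s.mapBA[b0] = -1;
      if (s.best >= maxpos) break;
    }
  }

  return List::create(_["size"] = s.best,
                      _["expansions"] = (double)s.expansions,
                      _["capped"] = s.capped);
}
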