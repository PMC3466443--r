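// Core graph algorithms for 2D chemical graphs: subgraph monomorphism,
// maximum common connected substructure, canonical codes, shortest paths.
//
// Molecules arrive from R as a packed list:
//   elem: integer atomic numbers; chg: integer formal charges;
//   arom: logical aromatic flags; bi, bj: 0-based bond endpoints;
//   bo:   integer bond orders (1, 2, 3; 4 = aromatic).
// Matching policy: atoms compatible iff (element, aromatic flag) equal;
// bonds compatible iff orders equal, aromatic being its own order.
// Formal charge is deliberately not matched.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Mol {
  int n;
  std::vector<int> elem, chg;
  std::vector<char> arom;
  std::vector<int> deg;
  // dense order matrix, 0 = not bonded (n is small: molecules, not proteins)
  std::vector<uint8_t> ord;
  std::vector<std::vector<int>> adj;
  int order(int i, int j) const { return ord[(size_t)i * n + j]; }
};

Mol unpack(const List& m) {
  Mol g;
  IntegerVector elem = m["elem"], chg = m["chg"], bi = m["bi"], bj = m["bj"], bo = m["bo"];
  LogicalVector arom = m["arom"];
  g.n = elem.size();
  g.elem.assign(elem.begin(), elem.end());
  g.chg.assign(chg.begin(), chg.end());
  g.arom.resize(g.n);
  for (int i = 0; i < g.n; ++i) g.arom[i] = arom[i] ? 1 : 0;
  g.deg.assign(g.n, 0);
  g.ord.assign((size_t)g.n * g.n, 0);
  g.adj.assign(g.n, {});
  for (int k = 0; k < bi.size(); ++k) {
    int i = bi[k], j = bj[k], o = bo[k];
    g.ord[(size_t)i * g.n + j] = (uint8_t)o;
    g.ord[(size_t)j * g.n + i] = (uint8_t)o;
    g.adj[i].push_back(j);
    g.adj[j].push_back(i);
    g.deg[i]++; g.deg[j]++;
  }
  return g;
}

bool atomCompat(const Mol& q, int a, const Mol& t, int b) {
  return q.elem[a] == t.elem[b] && q.arom[a] == t.arom[b];
}

// ---- subgraph monomorphism (VF2-flavoured backtracking) ----

struct Matcher {
  const Mol& q; const Mol& t;
  std::vector<int> qorder;       // visit order over query atoms
  std::vector<int> map;          // query -> target (-1 unmapped)
  std::vector<char> used;        // target atom used
  bool found = false;

  Matcher(const Mol& q_, const Mol& t_) : q(q_), t(t_) {
    // BFS order, highest-degree root per component: mapped neighbours
    // anchor candidates early, pruning hard.
    std::vector<char> vis(q.n, 0);
    std::vector<int> idx(q.n);
    for (int i = 0; i < q.n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) { return q.deg[a] > q.deg[b]; });
    for (int r : idx) {
      if (vis[r]) continue;
      std::vector<int> queue{r}; vis[r] = 1;
      for (size_t h = 0; h < queue.size(); ++h) {
        int u = queue[h]; qorder.push_back(u);
        std::vector<int> nb = q.adj[u];
        std::sort(nb.begin(), nb.end(), [&](int a, int b) { return q.deg[a] > q.deg[b]; });
        for (int v : nb) if (!vis[v]) { vis[v] = 1; queue.push_back(v); }
      }
    }
    map.assign(q.n, -1);
    used.assign(t.n, 0);
  }

  bool feasible(int u, int v) {
    if (used[v] || !atomCompat(q, u, t, v)) return false;
    if (t.deg[v] < q.deg[u]) return false;
    for (int w : q.adj[u]) {
      int mv = map[w];
      if (mv >= 0 && t.order(v, mv) != q.order(u, w)) return false;
    }
    return true;
  }

  bool search(size_t pos) {
    if (pos == qorder.size()) return true;
    int u = qorder[pos];
    for (int v = 0; v < t.n; ++v) {
      if (!feasible(u, v)) continue;
      map[u] = v; used[v] = 1;
      if (search(pos + 1)) return true;
      map[u] = -1; used[v] = 0;
    }
    return false;
  }
};

bool isSub(const Mol& q, const Mol& t) {
  if (q.n > t.n) return false;
  Matcher m(q, t);
  return m.search(0);
}

// ---- fixed-width bitsets for the product-graph clique search ----

struct BitRows {
  int nbits, nw;
  std::vector<uint64_t> w;  // rows * nw words
  BitRows(int rows, int bits) : nbits(bits), nw((bits + 63) / 64), w((size_t)rows * ((bits + 63) / 64), 0) {}
  uint64_t* row(int r) { return &w[(size_t)r * nw]; }
  const uint64_t* row(int r) const { return &w[(size_t)r * nw]; }
  void set(int r, int b) { row(r)[b >> 6] |= (uint64_t)1 << (b & 63); }
};

inline int popcountWords(const uint64_t* a, int nw) {
  int c = 0;
  for (int i = 0; i < nw; ++i) c += __builtin_popcountll(a[i]);
  return c;
}

struct McsSearch {
  int N, nw, nA, nB;
  const BitRows& compat;   // c- or d-compatible
  const BitRows& cadj;     // c-adjacent (both bonded, equal order)
  std::vector<int> va, vb; // product vertex -> (atom in A, atom in B)
  int best;                // best clique size found so far
  std::vector<int> cur, bestClique;
  long long nodes = 0, budget;
  bool exact = true;

  McsSearch(int N_, int nA_, int nB_, const BitRows& cp, const BitRows& ca,
            std::vector<int> va_, std::vector<int> vb_, int lb, long long budget_)
    : N(N_), nw((N_ + 63) / 64), nA(nA_), nB(nB_), compat(cp), cadj(ca),
      va(std::move(va_)), vb(std::move(vb_)), best(lb), budget(budget_) {}

  // bound: clique can gain at most min(#distinct A atoms, #distinct B atoms)
  int boundPD(const uint64_t* P, const uint64_t* D) {
    std::vector<char> sa(nA, 0), sb(nB, 0);
    int ca = 0, cb = 0;
    for (int wi = 0; wi < nw; ++wi) {
      uint64_t bits = P[wi] | D[wi];
      while (bits) {
        int b = wi * 64 + __builtin_ctzll(bits);
        bits &= bits - 1;
        if (!sa[va[b]]) { sa[va[b]] = 1; ++ca; }
        if (!sb[vb[b]]) { sb[vb[b]] = 1; ++cb; }
      }
    }
    return std::min(ca, cb);
  }

  // restrict D to vertices c-reachable from P through candidate vertices:
  // anything else can never join a c-connected clique grown from C
  void reachPrune(const std::vector<uint64_t>& P, std::vector<uint64_t>& D) {
    std::vector<uint64_t> reach(P), frontier(P);
    bool grew = true;
    while (grew) {
      grew = false;
      std::vector<uint64_t> next(nw, 0);
      for (int wi = 0; wi < nw; ++wi) {
        uint64_t bits = frontier[wi];
        while (bits) {
          int v = wi * 64 + __builtin_ctzll(bits);
          bits &= bits - 1;
          const uint64_t* av = cadj.row(v);
          for (int k = 0; k < nw; ++k) next[k] |= av[k] & D[k] & ~reach[k];
        }
      }
      for (int k = 0; k < nw; ++k)
        if (next[k]) { reach[k] |= next[k]; grew = true; }
      frontier.swap(next);
    }
    for (int k = 0; k < nw; ++k) D[k] &= reach[k];
  }

  void recurse(std::vector<uint64_t>& P, std::vector<uint64_t>& D) {
    if (++nodes > budget) { exact = false; return; }
    int sz = (int)cur.size();
    if (sz > best) { best = sz; bestClique = cur; }
    reachPrune(P, D);
    if (boundPD(P.data(), D.data()) + sz <= best) return;
    std::vector<uint64_t> newP(nw), newD(nw);
    for (int wi = 0; wi < nw && exact; ++wi) {
      while (P[wi]) {
        int v = wi * 64 + __builtin_ctzll(P[wi]);
        P[wi] &= P[wi] - 1;  // exclude v from later branches at this level
        const uint64_t* cv = compat.row(v);
        const uint64_t* av = cadj.row(v);
        for (int k = 0; k < nw; ++k) {
          uint64_t pk = P[k], dk = D[k];
          newP[k] = (pk & cv[k]) | (dk & cv[k] & av[k]);
          newD[k] = dk & cv[k] & ~av[k];
        }
        cur.push_back(v);
        recurse(newP, newD);
        cur.pop_back();
        if (!exact) return;
        if (boundPD(P.data(), D.data()) + sz <= best) return;
      }
    }
  }
};

std::string canonicalCode(const Mol& g);

}  // namespace

// [[Rcpp::export(name = ".cpp_is_substructure")]]
bool cpp_is_substructure(List query, List target) {
  Mol q = unpack(query), t = unpack(target);
  if (q.n == 0) return true;
  if (t.n == 0) return false;
  return isSub(q, t);
}

// [[Rcpp::export(name = ".cpp_match_library")]]
LogicalVector cpp_match_library(List query, List mols) {
  Mol q = unpack(query);
  int n = mols.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    Mol t = unpack(mols[i]);
    out[i] = (q.n == 0) ? true : (t.n == 0 ? false : isSub(q, t));
  }
  return out;
}

// Maximum common connected substructure. Reports the exact maximum when its
// size is >= floor_size; otherwise only certifies size < floor_size
// (size slot = floor_size - 1, found = FALSE). Node budget caps the search;
// exact = FALSE flags a truncated (best-found-so-far) answer.
// [[Rcpp::export(name = ".cpp_mcs")]]
List cpp_mcs(List a, List b, int floor_size, double node_budget) {
  Mol A = unpack(a), B = unpack(b);
  std::vector<int> va, vb;
  for (int i = 0; i < A.n; ++i)
    for (int j = 0; j < B.n; ++j)
      if (atomCompat(A, i, B, j)) { va.push_back(i); vb.push_back(j); }
  int N = (int)va.size();
  if (N == 0)
    return List::create(_["size"] = 0, _["amap"] = IntegerVector(0),
                        _["bmap"] = IntegerVector(0), _["found"] = (floor_size <= 0),
                        _["exact"] = true);
  // Any pair of product vertices on distinct atoms is compatible (the common
  // subgraph may omit bonds: embedding is a monomorphism, not induced);
  // c-edges connect pairs whose two sides share a bond of equal order.
  BitRows compat(N, N), cadj(N, N);
  for (int u = 0; u < N; ++u)
    for (int v = u + 1; v < N; ++v) {
      if (va[u] == va[v] || vb[u] == vb[v]) continue;
      compat.set(u, v); compat.set(v, u);
      int oa = A.order(va[u], va[v]), ob = B.order(vb[u], vb[v]);
      if (oa > 0 && oa == ob) { cadj.set(u, v); cadj.set(v, u); }
    }
  int lb = std::max(0, floor_size - 1);
  McsSearch s(N, A.n, B.n, compat, cadj, va, vb, lb, (long long)node_budget);
  int nw = (N + 63) / 64;
  std::vector<uint64_t> avail(nw, 0);
  for (int v = 0; v < N; ++v) avail[v >> 6] |= (uint64_t)1 << (v & 63);
  std::vector<uint64_t> P(nw), D(nw);
  for (int v = 0; v < N && s.exact; ++v) {
    avail[v >> 6] &= ~((uint64_t)1 << (v & 63));
    if (std::min(A.n, B.n) <= s.best) break;
    const uint64_t* cv = compat.row(v);
    const uint64_t* av = cadj.row(v);
    for (int k = 0; k < nw; ++k) { P[k] = avail[k] & cv[k] & av[k]; D[k] = avail[k] & cv[k] & ~av[k]; }
    s.cur.assign(1, v);
    s.recurse(P, D);
  }
  bool found = (int)s.bestClique.size() >= std::max(1, floor_size);
  IntegerVector amap, bmap;
  int size = found ? (int)s.bestClique.size() : lb;
  if (found) {
    amap = IntegerVector(s.bestClique.size());
    bmap = IntegerVector(s.bestClique.size());
    for (size_t k = 0; k < s.bestClique.size(); ++k) {
      amap[k] = va[s.bestClique[k]];
      bmap[k] = vb[s.bestClique[k]];
    }
  }
  return List::create(_["size"] = size, _["amap"] = amap, _["bmap"] = bmap,
                      _["found"] = found, _["exact"] = s.exact);
}

// All-pairs shortest path (bond count); -1 = different fragments.
// [[Rcpp::export(name = ".cpp_dist_matrix")]]
IntegerMatrix cpp_dist_matrix(int n, IntegerVector bi, IntegerVector bj) {
  std::vector<std::vector<int>> adj(n);
  for (int k = 0; k < bi.size(); ++k) {
    adj[bi[k]].push_back(bj[k]);
    adj[bj[k]].push_back(bi[k]);
  }
  IntegerMatrix d(n, n);
  std::fill(d.begin(), d.end(), -1);
  std::vector<int> q(n);
  for (int s = 0; s < n; ++s) {
    int head = 0, tail = 0;
    q[tail++] = s; d(s, s) = 0;
    while (head < tail) {
      int u = q[head++];
      for (int v : adj[u]) if (d(s, v) < 0) { d(s, v) = d(s, u) + 1; q[tail++] = v; }
    }
  }
  return d;
}

// TRUE for bonds that lie on a cycle (non-bridges), via DFS lowpoints.
// [[Rcpp::export(name = ".cpp_ring_bonds")]]
LogicalVector cpp_ring_bonds(int n, IntegerVector bi, IntegerVector bj) {
  int m = bi.size();
  std::vector<std::vector<std::pair<int,int>>> adj(n);  // (neighbour, bond idx)
  for (int k = 0; k < m; ++k) {
    adj[bi[k]].push_back({bj[k], k});
    adj[bj[k]].push_back({bi[k], k});
  }
  LogicalVector ring(m);
  std::fill(ring.begin(), ring.end(), true);
  std::vector<int> disc(n, -1), low(n, 0);
  int timer = 0;
  // iterative DFS to avoid deep recursion on long chains
  struct Frame { int u, pe; size_t i; };
  for (int s = 0; s < n; ++s) {
    if (disc[s] >= 0) continue;
    std::vector<Frame> st{{s, -1, 0}};
    disc[s] = low[s] = timer++;
    while (!st.empty()) {
      Frame& f = st.back();
      if (f.i < adj[f.u].size()) {
        auto [v, e] = adj[f.u][f.i++];
        if (e == f.pe) continue;
        if (disc[v] < 0) {
          disc[v] = low[v] = timer++;
          st.push_back({v, e, 0});
        } else {
          low[f.u] = std::min(low[f.u], disc[v]);
        }
      } else {
        int u = f.u, pe = f.pe;
        st.pop_back();
        if (!st.empty()) {
          int p = st.back().u;
          low[p] = std::min(low[p], low[u]);
          if (low[u] > disc[p]) ring[pe] = false;  // bridge
        }
      }
    }
  }
  return ring;
}

namespace {

// ---- canonical code: colour refinement + individualisation backtracking ----

std::vector<int> refine(const Mol& g, std::vector<int> col) {
  int n = g.n;
  while (true) {
    std::vector<std::pair<std::vector<long long>, int>> sig(n);
    for (int i = 0; i < n; ++i) {
      std::vector<long long> s{col[i]};
      std::vector<long long> nb;
      for (int j : g.adj[i]) nb.push_back((long long)g.order(i, j) * 1000003LL + col[j]);
      std::sort(nb.begin(), nb.end());
      s.insert(s.end(), nb.begin(), nb.end());
      sig[i] = {std::move(s), i};
    }
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) { return sig[a].first < sig[b].first; });
    std::vector<int> ncol(n);
    int c = 0;
    for (int k = 0; k < n; ++k) {
      if (k > 0 && sig[idx[k]].first != sig[idx[k - 1]].first) ++c;
      ncol[idx[k]] = c;
    }
    if (ncol == col) return col;
    col = std::move(ncol);
  }
}

std::string codeFromOrder(const Mol& g, const std::vector<int>& col) {
  int n = g.n;
  std::vector<int> pos(n);  // atom -> canonical position
  std::vector<int> atoms(n);
  for (int i = 0; i < n; ++i) atoms[col[i]] = i;
  for (int p = 0; p < n; ++p) pos[atoms[p]] = p;
  std::string out;
  out.reserve(n * 8);
  for (int p = 0; p < n; ++p) {
    int i = atoms[p];
    out += std::to_string(g.elem[i]) + "," + std::to_string(g.chg[i]) + "," + (g.arom[i] ? "1" : "0") + ";";
  }
  std::vector<std::array<int,3>> bonds;
  for (int i = 0; i < n; ++i)
    for (int j : g.adj[i])
      if (pos[i] < pos[j]) bonds.push_back({pos[i], pos[j], g.order(i, j)});
  std::sort(bonds.begin(), bonds.end());
  out += "|";
  for (auto& b : bonds)
    out += std::to_string(b[0]) + "-" + std::to_string(b[1]) + ":" + std::to_string(b[2]) + ";";
  return out;
}

void canonSearch(const Mol& g, std::vector<int> col, std::string& best, long long& budget) {
  if (--budget < 0) return;
  col = refine(g, col);
  int n = g.n;
  // locate first colour class with > 1 member
  std::vector<int> count(n, 0);
  for (int c : col) count[c]++;
  int target = -1;
  for (int c = 0; c < n; ++c) if (count[c] > 1) { target = c; break; }
  if (target < 0) {
    std::string code = codeFromOrder(g, col);
    if (best.empty() || code < best) best = code;
    return;
  }
  for (int i = 0; i < n; ++i) {
    if (col[i] != target) continue;
    std::vector<int> ncol(n);
    for (int j = 0; j < n; ++j) ncol[j] = col[j] * 2 + (col[j] >= target ? 2 : 0);
    ncol[i] = target * 2 + 1;  // individualise i just below its class
    canonSearch(g, ncol, best, budget);
  }
}

std::string canonicalCode(const Mol& g) {
  if (g.n == 0) return "empty";
  std::vector<long long> keys(g.n);
  std::vector<int> idx(g.n), col(g.n);
  for (int i = 0; i < g.n; ++i) {
    keys[i] = ((long long)g.elem[i] * 16 + (g.chg[i] + 8)) * 2 + (g.arom[i] ? 1 : 0);
    idx[i] = i;
  }
  std::sort(idx.begin(), idx.end(), [&](int a, int b) { return keys[a] < keys[b]; });
  int c = 0;
  for (int k = 0; k < g.n; ++k) {
    if (k > 0 && keys[idx[k]] != keys[idx[k - 1]]) ++c;
    col[idx[k]] = c;
  }
  std::string best;
  long long budget = 200000;  // molecules have tiny automorphism groups in practice
  canonSearch(g, col, best, budget);
  return best;
}

}  // namespace

// Canonical string code: equal iff graphs are isomorphic under the
// (element, charge, aromatic, bond order) labelling.
// [[Rcpp::export(name = ".cpp_canonical_code")]]
std::string cpp_canonical_code(List m) {
  return canonicalCode(unpack(m));
}
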