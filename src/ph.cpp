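// Vietoris-Rips persistent homology (dimensions 0 and 1) of a symmetric
// dissimilarity matrix, on the clique complex up to triangles.
//
// Dim 0: union-find over edges sorted by filtration value.  All n vertices
// are born at 0; each component merge kills one bar at the merging edge's
// value; exactly one bar is infinite.  Zero-length dim-0 bars are kept so
// the barcode always has n bars.
//
// Dim 1: standard persistence pairing by column reduction over GF(2) of the
// triangle boundary matrix in the edge basis.  A triangle enters the
// filtration at the maximum of its three edge values; the reduced pivot edge
// (the cycle-creating edge) gives the birth, the triangle the death.
// Zero-persistence dim-1 pairs are dropped.

#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

struct UF {
  std::vector<int> parent;
  explicit UF(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a);
    b = find(b);
    if (a == b) return false;
    parent[b] = a;
    return true;
  }
};

// XOR (symmetric difference) of two ascending index vectors
static std::vector<int> sym_diff(const std::vector<int>& a,
                                 const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  return out;
}

// [[Rcpp::export]]
List cpp_rips_ph(NumericMatrix Md, int max_dim) {
  const int n = Md.nrow();
  if (Md.ncol() != n) stop("matrix must be square");
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (!R_finite(Md(i, j))) stop("matrix entries must be finite");
      if (i < j && std::fabs(Md(i, j) - Md(j, i)) > 1e-12)
        stop("matrix must be symmetric");
    }

  // ---- edges sorted by (value, i, j) ----
  const int E = n * (n - 1) / 2;
  std::vector<double> eval(E);
  std::vector<int> ei(E), ej(E), eord(E);
  {
    int e = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j, ++e) {
        eval[e] = Md(i, j);
        ei[e] = i;
        ej[e] = j;
      }
  }
  for (int e = 0; e < E; ++e) eord[e] = e;
  std::sort(eord.begin(), eord.end(), [&](int a, int b) {
    if (eval[a] != eval[b]) return eval[a] < eval[b];
    if (ei[a] != ei[b]) return ei[a] < ei[b];
    return ej[a] < ej[b];
  });
  // filtration index of each raw edge
  std::vector<int> fidx(E);
  for (int k = 0; k < E; ++k) fidx[eord[k]] = k;
  // raw edge id from (i, j), i < j
  std::vector<int> raw(n * n, -1);
  {
    int e = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j, ++e) raw[i * n + j] = e;
  }

  std::vector<int> bar_dim;
  std::vector<double> bar_birth, bar_death;

  // ---- dimension 0 ----
  UF uf(n);
  std::vector<bool> is_mst(E, false);
  for (int k = 0; k < E; ++k) {
    int e = eord[k];
    if (uf.unite(ei[e], ej[e])) {
      is_mst[e] = true;
      bar_dim.push_back(0);
      bar_birth.push_back(0.0);
      bar_death.push_back(eval[e]);
    }
  }
  bar_dim.push_back(0);
  bar_birth.push_back(0.0);
  bar_death.push_back(R_PosInf);

  // ---- dimension 1 ----
  if (max_dim >= 1 && n >= 3) {
    struct Tri {
      double val;
      int e1, e2, e3;  // edge filtration indices, ascending
    };
    std::vector<Tri> tris;
    tris.reserve(static_cast<size_t>(n) * (n - 1) * (n - 2) / 6);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        for (int k = j + 1; k < n; ++k) {
          int a = fidx[raw[i * n + j]];
          int b = fidx[raw[i * n + k]];
          int c = fidx[raw[j * n + k]];
          int lo = std::min(a, std::min(b, c));
          int hi = std::max(a, std::max(b, c));
          int mid = a + b + c - lo - hi;
          int ehi = eord[hi];
          tris.push_back({eval[ehi], lo, mid, hi});
        }
    std::sort(tris.begin(), tris.end(), [](const Tri& x, const Tri& y) {
      if (x.val != y.val) return x.val < y.val;
      if (x.e3 != y.e3) return x.e3 < y.e3;
      if (x.e2 != y.e2) return x.e2 < y.e2;
      return x.e1 < y.e1;
    });

    // pivot (edge filtration index) -> reduced column
    std::unordered_map<int, std::vector<int>> cols;
    cols.reserve(E);
    std::unordered_map<int, double> pivot_death;
    std::vector<int> col;
    for (const Tri& t : tris) {
      col = {t.e1, t.e2, t.e3};
      while (!col.empty()) {
        int piv = col.back();
        auto it = cols.find(piv);
        if (it == cols.end()) break;
        col = sym_diff(col, it->second);
      }
      if (!col.empty()) {
        int piv = col.back();
        cols.emplace(piv, col);
        double birth = eval[eord[piv]];
        if (t.val > birth) {
          bar_dim.push_back(1);
          bar_birth.push_back(birth);
          bar_death.push_back(t.val);
        }
        pivot_death[piv] = t.val;
      }
    }
    // cycle-creating edges never killed -> infinite bars (cannot occur for a
    // complete finite matrix, but kept for generality)
    for (int e = 0; e < E; ++e) {
      if (!is_mst[e] && pivot_death.find(fidx[e]) == pivot_death.end()) {
        bar_dim.push_back(1);
        bar_birth.push_back(eval[e]);
        bar_death.push_back(R_PosInf);
      }
    }
  }

  return List::create(_["dim"] = wrap(bar_dim), _["birth"] = wrap(bar_birth),
                      _["death"] = wrap(bar_death));
}
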