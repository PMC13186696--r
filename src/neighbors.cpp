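#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, std::vector<int> &rnk, int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a == b) return;
  if (rnk[a] < rnk[b]) std::swap(a, b);
  parent[b] = a;
  if (rnk[a] == rnk[b]) rnk[a]++;
}

static inline int64_t cell_key(int64_t cx, int64_t cy) {
  // interleave-free key; grids here are far smaller than 2^31 cells per axis
  return (cx << 32) ^ (cy & 0xffffffffLL);
}

//' Connected components of points linked at distance <= r.
//'
//' Grid-hashed: each point is compared only against points in its own and the
//' eight adjacent cells of an r-sized grid, then merged by union-find.
//' Returns 1-based component labels in input order.
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_radius_components(NumericVector x, NumericVector y, double r) {
  const int n = x.size();
  IntegerVector out(n);
  if (n == 0) return out;
  std::vector<int> parent(n), rnk(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;

  if (r > 0) {
    const double r2 = r * r;
    std::unordered_map<int64_t, std::vector<int>> grid;
    grid.reserve(n * 2);
    std::vector<int64_t> cxs(n), cys(n);
    for (int i = 0; i < n; ++i) {
      cxs[i] = (int64_t)std::floor(x[i] / r);
      cys[i] = (int64_t)std::floor(y[i] / r);
      grid[cell_key(cxs[i], cys[i])].push_back(i);
    }
    for (int i = 0; i < n; ++i) {
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          auto it = grid.find(cell_key(cxs[i] + dx, cys[i] + dy));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            const double ddx = x[i] - x[j], ddy = y[i] - y[j];
            if (ddx * ddx + ddy * ddy <= r2) uf_union(parent, rnk, i, j);
          }
        }
      }
    }
  }

  // compact labels to 1..k in order of first appearance
  std::unordered_map<int, int> relabel;
  relabel.reserve(n);
  int next = 1;
  for (int i = 0; i < n; ++i) {
    int root = uf_find(parent, i);
    auto it = relabel.find(root);
    if (it == relabel.end()) {
      relabel[root] = next;
      out[i] = next++;
    } else {
      out[i] = it->second;
    }
  }
  return out;
}

//' First nearest-neighbour distance from each source point to the target set.
//'
//' Plane-sweep over targets sorted by x: for each source the window of
//' candidate targets is expanded outward until the x-gap alone exceeds the
//' best distance found. When same_set is true the i-th source is assumed to
//' be the i-th target and is excluded from its own search.
//' Returns NA for a source with no admissible target.
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericVector sx, NumericVector sy,
                          NumericVector tx, NumericVector ty,
                          bool same_set) {
  const int ns = sx.size(), nt = tx.size();
  NumericVector out(ns, NA_REAL);
  if (nt == 0 || (same_set && nt < 2)) return out;

  std::vector<int> ord(nt);
  for (int i = 0; i < nt; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return tx[a] < tx[b]; });
  std::vector<double> sxx(nt), syy(nt);
  for (int i = 0; i < nt; ++i) { sxx[i] = tx[ord[i]]; syy[i] = ty[ord[i]]; }

  for (int i = 0; i < ns; ++i) {
    const double px = sx[i], py = sy[i];
    // first sorted index with x >= px
    int lo = (int)(std::lower_bound(sxx.begin(), sxx.end(), px) - sxx.begin());
    double best = R_PosInf;
    int left = lo - 1, right = lo;
    while (left >= 0 || right < nt) {
      bool go_right;
      if (left < 0) go_right = true;
      else if (right >= nt) go_right = false;
      else go_right = (px - sxx[left]) > (sxx[right] - px);
      int k = go_right ? right : left;
      double gap = go_right ? (sxx[k] - px) : (px - sxx[k]);
      if (gap * gap > best) break;
      if (!(same_set && ord[k] == i)) {
        const double dx = sxx[k] - px, dy = syy[k] - py;
        const double d2 = dx * dx + dy * dy;
        if (d2 < best) best = d2;
      }
      if (go_right) ++right; else --left;
    }
    if (R_finite(best)) out[i] = std::sqrt(best);
  }
  return out;
}
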