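#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Agglomerative Ward clustering.
//
// Dissimilarities are initialised to squared Euclidean distances and, after
// each merge, recomputed with the Lance-Williams update using Ward's
// coefficients:
//   d(k, i+j) = [(n_i + n_k) d(k,i) + (n_j + n_k) d(k,j) - n_k d(i,j)]
//               / (n_i + n_j + n_k)
// Under this convention the merge height equals twice the increase in total
// within-cluster sum of squares, and heights are monotone non-decreasing.
// At every step the globally closest pair is merged; ties break towards the
// lexicographically smallest (min index, max index) pair. A per-cluster
// nearest-neighbour cache keeps the typical cost near O(n^2).
//
// Returns an hclust-style merge matrix (negative entries = leaves) plus
// heights.
// [[Rcpp::export]]
List cpp_ward(NumericMatrix x) {
  const int n = x.nrow(), p = x.ncol();
  if (n < 2) stop("ward_linkage needs at least 2 rows");

  std::vector<double> d((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < p; ++c) {
        double diff = x(i, c) - x(j, c);
        s += diff * diff;
      }
      d[(size_t)i * n + j] = s;
      d[(size_t)j * n + i] = s;
    }
  }

  std::vector<int> sz(n, 1);           // cluster sizes
  std::vector<int> step_id(n, 0);      // 0 = leaf, else merge step that formed it
  std::vector<bool> active(n, true);
  std::vector<int> nn(n, -1);          // nearest active neighbour (smallest index on ties)
  std::vector<double> nnd(n, 0.0);

  const double INF = std::numeric_limits<double>::infinity();
  auto recompute_nn = [&](int i) {
    double best = INF; int bj = -1;
    for (int j = 0; j < n; ++j) {
      if (j == i || !active[j]) continue;
      double v = d[(size_t)i * n + j];
      if (v < best) { best = v; bj = j; }
    }
    nn[i] = bj; nnd[i] = best;
  };
  for (int i = 0; i < n; ++i) recompute_nn(i);

  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1);

  for (int step = 1; step <= n - 1; ++step) {
    // globally closest active pair; scanning i ascending with strict '<'
    // yields the lexicographically smallest pair on ties because nn[i]
    // itself prefers the smallest index.
    double best = INF; int bi = -1;
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      double v = nnd[i];
      // orient so the cached pair is (min, max); nn may point backwards
      int a = i < nn[i] ? i : nn[i];
      if (v < best || (v == best && bi >= 0 && a < (bi < nn[bi] ? bi : nn[bi]))) {
        best = v; bi = i;
      }
    }
    int i = bi < nn[bi] ? bi : nn[bi];
    int j = bi < nn[bi] ? nn[bi] : bi;

    merge(step - 1, 0) = step_id[i] == 0 ? -(i + 1) : step_id[i];
    merge(step - 1, 1) = step_id[j] == 0 ? -(j + 1) : step_id[j];
    if (merge(step - 1, 0) > merge(step - 1, 1)) {
      int tmp = merge(step - 1, 0);
      merge(step - 1, 0) = merge(step - 1, 1);
      merge(step - 1, 1) = tmp;
    }
    height[step - 1] = best;

    const double dij = d[(size_t)i * n + j];
    const double ni = sz[i], nj = sz[j];
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == i || k == j) continue;
      const double nk = sz[k];
      double v = ((ni + nk) * d[(size_t)k * n + i] +
                  (nj + nk) * d[(size_t)k * n + j] - nk * dij) /
                 (ni + nj + nk);
      d[(size_t)k * n + i] = v;
      d[(size_t)i * n + k] = v;
    }
    active[j] = false;
    sz[i] += sz[j];
    step_id[i] = step;

    // refresh caches: the merged cluster, and any cluster whose cached
    // neighbour or distance was invalidated by the merge.
    recompute_nn(i);
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == i) continue;
      if (nn[k] == i || nn[k] == j) {
        recompute_nn(k);
      } else if (d[(size_t)k * n + i] < nnd[k] ||
                 (d[(size_t)k * n + i] == nnd[k] && i < nn[k])) {
        nn[k] = i; nnd[k] = d[(size_t)k * n + i];
      }
    }
  }

  return List::create(_["merge"] = merge, _["height"] = height);
}
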