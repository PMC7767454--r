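#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static inline double dist2_to_center(const NumericMatrix& x, int i,
                                     const std::vector<double>& cent,
                                     int c, int p) {
  double s = 0.0;
  for (int a = 0; a < p; ++a) {
    double diff = x(i, a) - cent[(size_t)c * p + a];
    s += diff * diff;
  }
  return s;
}

// K-means with Hartigan's single-point transfer criterion.
//
// Starting from the supplied initial centres (row indices), points are
// assigned to their nearest centre; any cluster left empty is re-seeded with
// the point farthest from its own centroid. Then passes over the data move a
// point from cluster c to cluster t whenever the size-corrected change
//   n_t/(n_t+1) * ||x - m_t||^2  <  n_c/(n_c-1) * ||x - m_c||^2
// strictly reduces the total within-cluster sum of squares, updating both
// centroids incrementally. The result is Hartigan-stable: no single-point
// reassignment can reduce the WCSS. Scan order is fixed, so the outcome is
// deterministic given the initial centres.
// [[Rcpp::export]]
List cpp_hartigan_wong(NumericMatrix x, IntegerVector init, int max_pass = 200) {
  const int n = x.nrow(), p = x.ncol(), k = init.size();
  if (k < 1 || k > n) stop("need 1 <= k <= n");

  std::vector<double> cent((size_t)k * p);
  for (int c = 0; c < k; ++c) {
    int r = init[c] - 1;
    if (r < 0 || r >= n) stop("initial centre index out of range");
    for (int a = 0; a < p; ++a) cent[(size_t)c * p + a] = x(r, a);
  }

  std::vector<int> lab(n), cnt(k, 0);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bc = 0;
    for (int c = 0; c < k; ++c) {
      double v = dist2_to_center(x, i, cent, c, p);
      if (v < best) { best = v; bc = c; }
    }
    lab[i] = bc; cnt[bc]++;
  }

  auto recompute_centroids = [&]() {
    std::fill(cent.begin(), cent.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) {
      cnt[lab[i]]++;
      for (int a = 0; a < p; ++a) cent[(size_t)lab[i] * p + a] += x(i, a);
    }
    for (int c = 0; c < k; ++c)
      if (cnt[c] > 0)
        for (int a = 0; a < p; ++a) cent[(size_t)c * p + a] /= cnt[c];
  };
  recompute_centroids();

  // re-seed empty clusters deterministically from the farthest point
  for (int guard = 0; guard < k; ++guard) {
    int empty = -1;
    for (int c = 0; c < k; ++c) if (cnt[c] == 0) { empty = c; break; }
    if (empty < 0) break;
    double worst = -1.0; int wi = -1;
    for (int i = 0; i < n; ++i) {
      if (cnt[lab[i]] <= 1) continue;
      double v = dist2_to_center(x, i, cent, lab[i], p);
      if (v > worst) { worst = v; wi = i; }
    }
    if (wi < 0) stop("cannot re-seed empty cluster");
    cnt[lab[wi]]--; lab[wi] = empty; cnt[empty]++;
    recompute_centroids();
  }

  const double EPS = 1e-12;
  int pass = 0;
  bool moved = true;
  while (moved && pass < max_pass) {
    moved = false;
    ++pass;
    for (int i = 0; i < n; ++i) {
      int c = lab[i];
      if (cnt[c] == 1) continue;   // moving it would empty the cluster
      double r1 = (double)cnt[c] / (cnt[c] - 1) * dist2_to_center(x, i, cent, c, p);
      double bestGain = std::numeric_limits<double>::infinity();
      int bt = -1;
      for (int t = 0; t < k; ++t) {
        if (t == c) continue;
        double r2 = (double)cnt[t] / (cnt[t] + 1) * dist2_to_center(x, i, cent, t, p);
        if (r2 < bestGain) { bestGain = r2; bt = t; }
      }
      if (bt >= 0 && bestGain < r1 - EPS) {
        for (int a = 0; a < p; ++a) {
          cent[(size_t)c * p + a] =
            (cent[(size_t)c * p + a] * cnt[c] - x(i, a)) / (cnt[c] - 1);
          cent[(size_t)bt * p + a] =
            (cent[(size_t)bt * p + a] * cnt[bt] + x(i, a)) / (cnt[bt] + 1);
        }
        cnt[c]--; cnt[bt]++;
        lab[i] = bt;
        moved = true;
      }
    }
  }

  recompute_centroids();           // numerical hygiene before reporting
  double wcss = 0.0;
  for (int i = 0; i < n; ++i) wcss += dist2_to_center(x, i, cent, lab[i], p);

  NumericMatrix centers(k, p);
  for (int c = 0; c < k; ++c)
    for (int a = 0; a < p; ++a) centers(c, a) = cent[(size_t)c * p + a];
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) labels[i] = lab[i] + 1;

  return List::create(_["labels"] = labels, _["centers"] = centers,
                      _["wcss"] = wcss, _["passes"] = pass,
                      _["converged"] = !moved);
}
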