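test_that("Ward linkage reproduces hand-computed merges and the n = 2 case", {
  tw <- ward_linkage(cbind(c(0, 1, 10)))
  # first merge {0,1} at squared distance 1; then with {10} at 2x the SS increase
  expect_equal(tw$height, c(1, 361 / 3), tolerance = 1e-12)
  expect_equal(labels_to_partition(cut_tree(tw, 2)$labels),
               list(c(1L, 2L), 3L))
  t2 <- ward_linkage(cbind(c(0, 3)))
  expect_equal(t2$height, 9)              # squared pairwise distance convention
  expect_error(ward_linkage(cbind(1)), "at least 2")
})

test_that("Ward agrees with the exhaustive minimum-variance oracle on random instances", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:8, 1); p <- sample(1:3, 1)
    x <- matrix(rnorm(n * p), n, p)
    tw <- ward_linkage(x)
    nv <- naive_ward(x)
    expect_equal(tw$height, nv$heights, tolerance = 1e-8)
    for (k in 2:(n - 1)) {
      expect_identical(labels_to_partition(cut_tree(tw, k)$labels),
                       nv$partitions[[n - k]])
    }
    expect_true(all(diff(tw$height) >= -1e-10))   # monotone heights
  }
})

test_that("Ward heights match stats::hclust on squared distances", {
  set.seed(32)
  x <- matrix(rnorm(60 * 3), 60, 3)
  tw <- ward_linkage(x)
  hc <- stats::hclust(dist(x)^2, method = "ward.D")
  expect_equal(tw$height, hc$height, tolerance = 1e-8)
  for (k in c(2, 4, 7)) {
    expect_identical(labels_to_partition(cut_tree(tw, k)$labels),
                     labels_to_partition(unname(cutree(hc, k))))
  }
})

test_that("cut_tree spans k = 1 to k = n", {
  x <- cbind(c(0, 1, 10, 11, 20))
  tw <- ward_linkage(x)
  expect_equal(cut_tree(tw, 1)$labels, rep(1L, 5))
  expect_equal(sort(cut_tree(tw, 5)$labels), 1:5)
  expect_equal(cut_tree(tw, 5)$wcss, 0)
  expect_error(cut_tree(tw, 0), "k must")
  expect_error(cut_tree(tw, 6), "k must")
})

test_that("Hartigan-Wong k-means solves the 1-D toy exactly and respects limits", {
  km <- kmeans_hartigan_wong(cbind(c(0, 1, 10, 11)), 2, seed = 1)
  expect_equal(sort(as.numeric(km$centroids)), c(0.5, 10.5))
  expect_equal(km$wcss, 1)
  expect_equal(kmeans_hartigan_wong(cbind(rnorm(6)), 6, seed = 1)$wcss, 0)
  expect_error(kmeans_hartigan_wong(cbind(1:3), 4), "k must")
  set.seed(9); xr <- matrix(rnorm(40), 20, 2)
  expect_identical(kmeans_hartigan_wong(xr, 3, seed = 5)$labels,
                   kmeans_hartigan_wong(xr, 3, seed = 5)$labels)
})

test_that("k-means reaches the exhaustive-partition optimum on random instances", {
  set.seed(33)
  for (rep in 1:15) {
    n <- sample(5:9, 1); k <- sample(2:3, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    km <- kmeans_hartigan_wong(x, k, n_restarts = 50, seed = rep)
    expect_equal(km$wcss, brute_kmeans_wcss(x, k), tolerance = 1e-8)
    # Hartigan stability: no single-point transfer lowers the WCSS
    cnt <- tabulate(km$labels, k)
    for (i in seq_len(n)) {
      c <- km$labels[i]
      if (cnt[c] == 1) next
      r1 <- cnt[c] / (cnt[c] - 1) * sum((x[i, ] - km$centroids[c, ])^2)
      for (t in setdiff(seq_len(k), c)) {
        r2 <- cnt[t] / (cnt[t] + 1) * sum((x[i, ] - km$centroids[t, ])^2)
        expect_gte(r2, r1 - 1e-8)
      }
    }
  }
})

test_that("k-means matches the reference implementation on well-separated data", {
  set.seed(34)
  x <- rbind(matrix(rnorm(40, 0, 0.3), ncol = 2),
             matrix(rnorm(40, 5, 0.3), ncol = 2),
             matrix(rnorm(40, c(0, 10), 0.3), ncol = 2))
  km <- kmeans_hartigan_wong(x, 3, n_restarts = 20, seed = 2)
  ref <- stats::kmeans(x, 3, nstart = 20, algorithm = "Hartigan-Wong")
  expect_equal(km$wcss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("connectivity matches its definition and is monotone in L", {
  # two tight, far-apart clusters: nothing penalised
  x <- cbind(c(0, 0.1, 10, 10.1))
  expect_equal(connectivity(x, c(1, 1, 2, 2), 1), 0)
  # {0, 10} split apart: each point's nearest neighbour is in the other cluster
  expect_equal(connectivity(cbind(c(0, 10)), c(1, 2), 1), 2)
  set.seed(35)
  xr <- matrix(rnorm(40), 20, 2)
  lab <- sample(1:3, 20, replace = TRUE)
  vals <- vapply(1:8, function(L) connectivity(xr, lab, L), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_error(connectivity(xr, lab, 20), "L < n")
})

test_that("silhouette width matches its definition, including degenerate cases", {
  sw <- silhouette_width(cbind(c(0, 0.1, 10, 10.1)), c(1, 1, 2, 2))
  expect_equal(sw$mean, 0.99, tolerance = 1e-2)
  expect_equal(sw$widths[2], (9.95 - 0.1) / 9.95, tolerance = 1e-9)
  # all points identical in 2 clusters: 0/0 -> 0 convention
  sw0 <- silhouette_width(cbind(rep(1, 4)), c(1, 1, 2, 2))
  expect_equal(sw0$widths, rep(0, 4))
  # singleton cluster gets 0
  sws <- silhouette_width(cbind(c(0, 1, 5)), c(1, 1, 2))
  expect_equal(sws$widths[3], 0)
  expect_error(silhouette_width(cbind(1:3), rep(1, 3)), "k = 1")
})

test_that("Dunn index matches its definition and is scale-invariant", {
  x <- cbind(c(0, 1, 10, 11))
  expect_equal(dunn_index(x, c(1, 1, 2, 2)), 9)
  # coincident points across clusters: zero separation
  expect_equal(dunn_index(cbind(c(0, 5, 5, 9)), c(1, 1, 2, 2)), 0)
  set.seed(36)
  xr <- matrix(rnorm(30), 15, 2)
  lab <- sample(1:3, 15, replace = TRUE)
  expect_equal(dunn_index(xr * 7.3, lab), dunn_index(xr, lab), tolerance = 1e-12)
  expect_equal(dunn_index(cbind(c(0, 5)), c(1, 2)), Inf)  # all-singleton sentinel
})

test_that("validation measures match direct-definition oracles on random labelings", {
  set.seed(37)
  for (rep in 1:10) {
    n <- sample(10:25, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(connectivity(x, lab, 5), direct_connectivity(x, lab, 5), tolerance = 1e-10)
    expect_equal(silhouette_width(x, lab)$widths, direct_silhouette(x, lab)$widths,
                 tolerance = 1e-10)
    expect_equal(dunn_index(x, lab), direct_dunn(x, lab), tolerance = 1e-10)
  }
})

test_that("selection recovers three well-separated blobs and is deterministic", {
  set.seed(38)
  x <- rbind(matrix(rnorm(120, 0, 1), ncol = 2),
             matrix(rnorm(120, 8, 1), ncol = 2),
             cbind(rnorm(60, 16), rnorm(60, 0)))
  s1 <- select_clustering(x, k_range = 2:6, seed = 4)
  expect_equal(s1$best$k, 3)
  s2 <- select_clustering(x, k_range = 2:6, seed = 4)
  expect_identical(s1$best$labels, s2$best$labels)
  expect_identical(s1$scores, s2$scores)
  expect_error(select_clustering(x, k_range = integer(0)), "k_range")
  # duplicated blob: silhouette prefers the 2-way split over slicing it in 4
  y <- rbind(matrix(rnorm(80, 0, 0.5), ncol = 2), matrix(rnorm(80, 6, 0.5), ncol = 2))
  sc <- select_clustering(y, k_range = c(2, 4), seed = 5)$scores
  expect_gt(sc$silhouette[sc$method == "ward" & sc$k == 2],
            sc$silhouette[sc$method == "ward" & sc$k == 4])
})

test_that("relabelling maps clusters onto the behavioural speed ordering", {
  rom <- c(0.1, 0.1, 2.0, 2.0, 0.6, 0.6)
  cr <- structure(list(labels = c(1L, 1L, 2L, 2L, 3L, 3L), k = 3L,
                       method = "kmeans", centroids = diag(3), wcss = 0, n = 6L),
                  class = "cluster_result")
  rl <- relabel_clusters(cr, rom)
  expect_equal(rl$labels, c(1L, 1L, 2L, 2L, 3L, 3L))   # already ordered
  cr2 <- cr; cr2$labels <- c(2L, 2L, 3L, 3L, 1L, 1L)   # scrambled raw labels
  rl2 <- relabel_clusters(cr2, rom)
  expect_equal(rl2$labels, c(1L, 1L, 2L, 2L, 3L, 3L))
  m <- vapply(1:3, function(k) mean(rom[rl2$labels == k]), numeric(1))
  expect_true(m[2] > m[3] && m[3] > m[1])
  # k != 3: ascending mean ROM
  cr4 <- structure(list(labels = c(2L, 1L), k = 2L, method = "kmeans",
                        centroids = diag(2), wcss = 0, n = 2L),
                   class = "cluster_result")
  expect_equal(relabel_clusters(cr4, c(5, 1))$labels, c(2L, 1L))
})
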