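# Internal cluster validation: connectivity, silhouette width, Dunn index,
# and rank-aggregated model selection over (method, k) candidates. All three
# measures use plain Euclidean distances on the feature matrix.

#' Connectivity of a clustering
#'
#' For each observation, its `n_neighbors` nearest Euclidean neighbours are
#' inspected; the j-th nearest contributes a penalty of `1/j` when it lies in
#' a different cluster. The measure is the total penalty: `>= 0`, lower is
#' better, and non-decreasing in `n_neighbors`. Neighbour ties are broken by
#' row order.
#'
#' @param x Numeric matrix of observations by features, or a precomputed
#'   symmetric distance matrix with attribute check disabled via
#'   `is_dist = TRUE`.
#' @param labels Integer cluster labels, one per row.
#' @param n_neighbors Neighbourhood size L (default 10), `1 <= L < n`.
#' @param is_dist Is `x` already a full distance matrix?
#' @return The connectivity score (single number).
#' @export
connectivity <- function(x, labels, n_neighbors = 10, is_dist = FALSE) {
  D <- .full_dist(x, is_dist)
  n <- nrow(D)
  stopifnot(length(labels) == n)
  if (n_neighbors < 1 || n_neighbors >= n) {
    stop("n_neighbors must satisfy 1 <= L < n")
  }
  nn <- .nearest_neighbours(D, n_neighbors)
  penalty <- 1 / seq_len(n_neighbors)
  total <- 0
  for (j in seq_len(n_neighbors)) {
    total <- total + penalty[j] * sum(labels[nn[, j]] != labels)
  }
  total
}

#' Silhouette widths of a clustering
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a(i)` is the mean distance
#' from i to the other members of its cluster and `b(i)` the smallest mean
#' distance to any other cluster. Observations in singleton clusters get
#' `s(i) = 0` by convention, as does the degenerate `0/0` case.
#'
#' @inheritParams connectivity
#' @return List with per-observation `widths` and their `mean`.
#' @export
silhouette_width <- function(x, labels, is_dist = FALSE) {
  D <- .full_dist(x, is_dist)
  n <- nrow(D)
  stopifnot(length(labels) == n)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("silhouette width is undefined for k = 1")
  sizes <- tabulate(match(labels, ks), nbins = length(ks))
  # mean distance from every point to every cluster (including its own)
  ind <- outer(labels, ks, "==") + 0
  sums <- D %*% ind
  meanall <- sweep(sums, 2, sizes, "/")
  own <- match(labels, ks)
  a <- (sums[cbind(seq_len(n), own)]) / pmax(sizes[own] - 1, 1)
  bmat <- meanall
  bmat[cbind(seq_len(n), own)] <- Inf
  b <- apply(bmat, 1, min)
  denom <- pmax(a, b)
  s <- ifelse(denom > 0, (b - a) / denom, 0)
  s[sizes[own] == 1] <- 0
  list(widths = as.numeric(s), mean = mean(s))
}

#' Dunn index of a clustering
#'
#' Minimum between-cluster separation (smallest inter-point distance across
#' any cluster pair) divided by the maximum cluster diameter (largest
#' intra-cluster distance). Higher is better; scale-invariant. If every
#' cluster is a singleton the diameter is zero and `Inf` is returned.
#'
#' @inheritParams connectivity
#' @return The Dunn index (single non-negative number, possibly `Inf`).
#' @export
dunn_index <- function(x, labels, is_dist = FALSE) {
  D <- .full_dist(x, is_dist)
  n <- nrow(D)
  stopifnot(length(labels) == n)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("Dunn index is undefined for k = 1")
  diam <- 0
  sep <- Inf
  for (ci in seq_along(ks)) {
    mi <- labels == ks[ci]
    if (sum(mi) > 1) diam <- max(diam, max(D[mi, mi]))
    for (cj in seq_along(ks)) {
      if (cj <= ci) next
      mj <- labels == ks[cj]
      sep <- min(sep, min(D[mi, mj]))
    }
  }
  if (diam == 0) return(Inf)
  sep / diam
}

.full_dist <- function(x, is_dist = FALSE) {
  if (is_dist) {
    D <- as.matrix(x)
    stopifnot(nrow(D) == ncol(D))
    return(D)
  }
  as.matrix(dist(as.matrix(x)))
}

# n x L matrix of nearest-neighbour indices (self excluded, ties by index).
.nearest_neighbours <- function(D, L) {
  n <- nrow(D)
  out <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    o <- order(D[i, ])
    o <- o[o != i]
    out[i, ] <- o[seq_len(L)]
  }
  out
}

#' Evaluate and select a clustering
#'
#' Fits every requested (method, k) candidate -- Ward trees cut at each k and
#' Hartigan-Wong K-means per k -- scores each with the three internal
#' validation measures, and returns the candidate with the best mean rank
#' (connectivity ascending, silhouette and Dunn descending). Remaining ties
#' break towards the smaller k, then towards the first method in `methods`.
#'
#' For very large tables (`n > hc_cap`) the Ward tree is built on a random
#' subsample (stratified by `animal` when given, an O(n^2) memory guard);
#' remaining rows are assigned to the nearest cluster centroid. K-means and
#' the validation measures always use the full table.
#'
#' @param x Numeric matrix of observations by features (use
#'   [feature_matrix()] for a feature table).
#' @param k_range Candidate cluster counts (default `2:6`), within `[2, n-1]`.
#' @param methods Subset of `c("ward", "kmeans")`.
#' @param n_restarts Restarts per K-means fit.
#' @param n_neighbors Neighbourhood size for [connectivity()].
#' @param seed Optional integer controlling K-means restarts and any
#'   subsampling; the caller's RNG state is untouched.
#' @param hc_cap Maximum rows clustered hierarchically before subsampling.
#' @param animal Optional vector (length n) of animal ids used to stratify
#'   the subsample.
#' @return A `cluster_selection`: list with `best` (a `cluster_result`),
#'   `scores` (data.frame: method, k, connectivity, silhouette, dunn, wcss,
#'   mean_rank) and `candidates` (all fitted `cluster_result`s).
#' @export
select_clustering <- function(x, k_range = 2:6, methods = c("ward", "kmeans"),
                              n_restarts = 25, n_neighbors = 10, seed = NULL,
                              hc_cap = 10000, animal = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (length(k_range) == 0) stop("k_range must not be empty")
  if (any(k_range < 2 | k_range > n - 1)) stop("k_range must lie within [2, n-1]")
  methods <- match.arg(methods, several.ok = TRUE)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }

  candidates <- list()
  if ("ward" %in% methods) {
    if (n > hc_cap) {
      idx <- .stratified_sample(n, hc_cap, animal)
      tree <- ward_linkage(x[idx, , drop = FALSE])
      for (k in k_range) {
        sub <- cut_tree(tree, k)
        labels <- .assign_nearest(x, sub$centroids)
        candidates[[paste0("ward_", k)]] <- .cluster_result(x, labels, k, "ward")
      }
    } else {
      tree <- ward_linkage(x)
      for (k in k_range) {
        candidates[[paste0("ward_", k)]] <- cut_tree(tree, k)
      }
    }
  }
  if ("kmeans" %in% methods) {
    for (k in k_range) {
      candidates[[paste0("kmeans_", k)]] <-
        kmeans_hartigan_wong(x, k, n_restarts = n_restarts)
    }
  }

  D <- as.matrix(dist(x))
  scores <- do.call(rbind, lapply(candidates, function(cr) {
    data.frame(method = cr$method, k = cr$k,
               connectivity = connectivity(D, cr$labels, n_neighbors, is_dist = TRUE),
               silhouette = silhouette_width(D, cr$labels, is_dist = TRUE)$mean,
               dunn = dunn_index(D, cr$labels, is_dist = TRUE),
               wcss = cr$wcss, stringsAsFactors = FALSE)
  }))
  rownames(scores) <- NULL
  scores$mean_rank <- (rank(scores$connectivity, ties.method = "average") +
                         rank(-scores$silhouette, ties.method = "average") +
                         rank(-scores$dunn, ties.method = "average")) / 3
  ord <- order(scores$mean_rank, scores$k, match(scores$method, methods))
  best_i <- ord[1]
  structure(list(best = candidates[[best_i]], scores = scores,
                 candidates = candidates),
            class = "cluster_selection")
}

.stratified_sample <- function(n, cap, animal) {
  if (is.null(animal)) return(sort(sample.int(n, cap)))
  stopifnot(length(animal) == n)
  groups <- split(seq_len(n), animal)
  per <- ceiling(cap / length(groups))
  idx <- unlist(lapply(groups, function(g) {
    if (length(g) <= per) g else sort(sample(g, per))
  }), use.names = FALSE)
  sort(idx)
}

.assign_nearest <- function(x, centroids) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centroids))) -
    2 * x %*% t(centroids) +
    outer(rep(1, nrow(x)), rowSums(centroids^2))
  as.integer(max.col(-d2, ties.method = "first"))
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat("<cluster_selection>\n")
  print(format(x$scores, digits = 4), row.names = FALSE)
  cat(sprintf("selected: %s with k = %d\n", x$best$method, x$best$k))
  invisible(x)
}

#' Relabel clusters to the behavioural numbering
#'
#' Raw cluster indices are arbitrary; this maps them onto the behavioural
#' codes of [behavior_states()] using the mean rate of movement per cluster.
#' For `k = 3`: slowest cluster becomes 1 (resting), fastest becomes 2
#' (traveling) and the intermediate becomes 3 (foraging), matching the
#' ordering of the cluster speed means. For any other k, clusters are
#' renumbered 1..k by ascending mean ROM.
#'
#' @param result A `cluster_result`.
#' @param rom Numeric vector of rate-of-movement values aligned with
#'   `result$labels`.
#' @return The `cluster_result` with remapped `labels` and an added `mapping`
#'   element (`mapping[old] = new`).
#' @export
relabel_clusters <- function(result, rom) {
  stopifnot(inherits(result, "cluster_result"), length(rom) == result$n)
  k <- result$k
  means <- vapply(seq_len(k), function(c) mean(rom[result$labels == c]), numeric(1))
  asc <- order(means)              # cluster indices, slowest first
  mapping <- integer(k)
  if (k == 3) {
    mapping[asc] <- c(1L, 3L, 2L)  # slowest -> 1, middle -> 3, fastest -> 2
  } else {
    mapping[asc] <- seq_len(k)
  }
  result$labels <- mapping[result$labels]
  result$centroids <- result$centroids[order(mapping), , drop = FALSE]
  result$mapping <- mapping
  result
}
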