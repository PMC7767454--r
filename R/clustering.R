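#' Agglomerative Ward clustering (Lance-Williams update)
#'
#' Builds the full merge tree from squared Euclidean distances, recomputing
#' between-cluster dissimilarities after each merge with the Lance-Williams
#' update under Ward's minimum-variance coefficients. At every stage the two
#' closest clusters are merged (ties towards the lexicographically smallest
#' index pair). Merge heights equal twice the increase in total
#' within-cluster sum of squares and are monotone non-decreasing.
#'
#' @param x Numeric matrix of observations (rows) by features (columns),
#'   typically the standardized matrix from [feature_matrix()]. `n >= 2`,
#'   no missing values.
#' @return A `ward_tree`: list with `merge` (hclust convention: negative
#'   entries are leaves), `height`, `n`, and the clustered data in `data`.
#' @seealso [cut_tree()], [as.hclust.ward_tree()]
#' @examples
#' tr <- ward_linkage(cbind(c(0, 1, 10)))
#' tr$height                          # 1, then 120.33
#' @export
ward_linkage <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2) stop("ward_linkage needs at least 2 rows")
  if (anyNA(x)) stop("ward_linkage input contains missing values")
  res <- cpp_ward(x)
  structure(list(merge = res$merge, height = as.numeric(res$height),
                 n = nrow(x), data = x),
            class = "ward_tree")
}

#' @export
print.ward_tree <- function(x, ...) {
  cat(sprintf("<ward_tree> %d observations, %d merges, height range [%.4g, %.4g]\n",
              x$n, length(x$height), min(x$height), max(x$height)))
  invisible(x)
}

#' Convert a ward_tree to an hclust object
#'
#' @param x A `ward_tree`.
#' @param ... Unused.
#' @return A `stats::hclust`-compatible object (method `"ward"`).
#' @export
as.hclust.ward_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = .tree_leaf_order(x$merge),
                 labels = NULL, method = "ward",
                 call = match.call(), dist.method = "squared euclidean"),
            class = "hclust")
}

# Leaf order by depth-first traversal of the merge matrix (iterative).
.tree_leaf_order <- function(merge) {
  n <- nrow(merge) + 1
  stack <- c(nrow(merge))       # merge-step indices; negative = leaf
  ord <- integer(0)
  while (length(stack) > 0) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (node < 0) {
      ord <- c(ord, -node)
    } else {
      stack <- c(stack, merge[node, 2], merge[node, 1])
    }
  }
  ord
}

#' Cut a Ward tree into k clusters
#'
#' Undoes the last `k - 1` merges. Labels are arbitrary 1..k (in order of
#' first appearance); use [relabel_clusters()] to map them to the behavioural
#' numbering.
#'
#' @param tree A `ward_tree`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return A `cluster_result`: list with `labels`, `k`, `method = "ward"`,
#'   `height_cut` (the height below which the tree was cut), `centroids` and
#'   `wcss`.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "ward_tree"))
  if (k < 1 || k > tree$n) stop("k must lie in [1, n]")
  labels <- as.integer(cutree(as.hclust(tree), k = k))
  height_cut <- if (k == 1) Inf else tree$height[tree$n - k]
  .cluster_result(tree$data, labels, k, "ward", height_cut = height_cut)
}

#' K-means clustering with the Hartigan-Wong algorithm
#'
#' Minimises the total within-cluster sum of squares by Hartigan's
#' single-point transfer rule: a point moves between clusters whenever the
#' size-corrected change `n_t/(n_t+1) ||x - m_t||^2 < n_c/(n_c-1) ||x - m_c||^2`
#' strictly lowers the WCSS, until no such move exists (a Hartigan-stable
#' partition). The best of `n_restarts` random initialisations (centres drawn
#' without replacement from the data rows) is returned; an initially empty
#' cluster is re-seeded from the point farthest from its own centroid.
#'
#' @param x Numeric matrix of observations by features, no missing values.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param n_restarts Number of random initialisations (default 25).
#' @param seed Optional integer; if supplied, restarts are derived from it
#'   and the caller's RNG state is untouched.
#' @return A `cluster_result`: list with `labels`, `k`, `method = "kmeans"`,
#'   `centroids`, `wcss` and `restart_wcss` (the optimum found by every
#'   restart).
#' @examples
#' km <- kmeans_hartigan_wong(cbind(c(0, 1, 10, 11)), k = 2, seed = 1)
#' km$wcss                            # 1
#' @export
kmeans_hartigan_wong <- function(x, k, n_restarts = 25, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (k < 1 || k > n) stop("k must lie in [1, n]")
  if (anyNA(x)) stop("kmeans input contains missing values")
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  best <- NULL
  restart_wcss <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- sample.int(n, k)
    fit <- cpp_hartigan_wong(x, init)
    restart_wcss[r] <- fit$wcss
    if (is.null(best) || fit$wcss < best$wcss - 1e-12) best <- fit
  }
  out <- .cluster_result(x, as.integer(best$labels), k, "kmeans",
                         centroids = best$centers)
  out$restart_wcss <- restart_wcss
  out
}

.cluster_result <- function(x, labels, k, method, centroids = NULL,
                            height_cut = NULL) {
  if (is.null(centroids)) {
    centroids <- do.call(rbind, lapply(seq_len(k), function(c) {
      colMeans(x[labels == c, , drop = FALSE])
    }))
  }
  wcss <- sum(vapply(seq_len(k), function(c) {
    m <- x[labels == c, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }, numeric(1)))
  structure(list(labels = labels, k = as.integer(k), method = method,
                 centroids = centroids, wcss = wcss, height_cut = height_cut,
                 n = length(labels)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s, k = %d, n = %d, WCSS = %.4g\n",
              x$method, x$k, x$n, x$wcss))
  cat("  sizes:", paste(tabulate(x$labels, nbins = x$k), collapse = ", "), "\n")
  invisible(x)
}
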