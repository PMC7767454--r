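# Independent brute-force / direct-definition oracles used to verify the
# clustering and statistics implementations on small instances. These are
# deliberately naive re-derivations from first principles and share no code
# with the package internals.

# Exhaustive Ward agglomeration: at every step recompute, for every pair of
# current clusters, twice the increase in total within-cluster sum of squares
# caused by merging them, and merge the minimum (ties: lexicographically
# smallest index pair). Returns the partition after every merge plus heights.
naive_ward <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  ss <- function(idx) {
    m <- x[idx, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        cost <- 2 * (ss(c(clusters[[i]], clusters[[j]])) -
                       ss(clusters[[i]]) - ss(clusters[[j]]))
        if (cost < best - 1e-12) { best <- cost; bi <- i; bj <- j }
      }
    }
    clusters[[bi]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    clusters[[bj]] <- NULL
    heights <- c(heights, best)
    partitions[[length(partitions) + 1]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# Canonical form of a partition (list of index sets) for comparison.
canon_partition <- function(p) {
  p <- lapply(p, sort)
  p[order(vapply(p, min, numeric(1)))]
}

# Partition of 1..n implied by integer labels.
labels_to_partition <- function(labels) {
  canon_partition(unname(split(seq_along(labels), labels)))
}

# Exhaustive K-means optimum: enumerate every assignment of n points to k
# non-empty clusters and take the minimum WCSS.
brute_kmeans_wcss <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(k^n <= 2e6)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    if (length(unique(assign)) == k) {
      w <- 0
      for (c in unique(assign)) {
        m <- x[assign == c, , drop = FALSE]
        w <- w + sum(sweep(m, 2, colMeans(m))^2)
      }
      if (w < best) best <- w
    }
    i <- 1L
    while (i <= n && assign[i] == k) { assign[i] <- 1L; i <- i + 1L }
    if (i > n) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# Direct-definition validation measures (plain loops over the definition).
direct_connectivity <- function(x, labels, L) {
  D <- as.matrix(dist(x))
  n <- nrow(D)
  total <- 0
  for (i in seq_len(n)) {
    o <- order(D[i, ])
    o <- o[o != i]
    for (j in seq_len(L)) {
      if (labels[o[j]] != labels[i]) total <- total + 1 / j
    }
  }
  total
}

direct_silhouette <- function(x, labels) {
  D <- as.matrix(dist(x))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(D[i, labels == cl]))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  list(widths = s, mean = mean(s))
}

direct_dunn <- function(x, labels) {
  D <- as.matrix(dist(x))
  cls <- unique(labels)
  diam <- 0; sep <- Inf
  for (ci in cls) {
    mi <- which(labels == ci)
    if (length(mi) > 1) diam <- max(diam, max(D[mi, mi]))
    for (cj in cls) {
      if (cj <= ci) next
      sep <- min(sep, min(D[mi, which(labels == cj), drop = FALSE]))
    }
  }
  if (diam == 0) Inf else sep / diam
}

# Textbook chi-squared homogeneity statistic.
direct_chisq <- function(counts) {
  e <- sum(counts) / length(counts)
  sum((counts - e)^2 / e)
}

# Explicit sequential sum-of-squares ANOVA with animal entered first.
direct_rm_anova <- function(values, cluster, animal) {
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  fit_a <- lm(values ~ factor(animal))
  ss_animal <- ss_total - sum(residuals(fit_a)^2)
  fit_ac <- lm(values ~ factor(animal) + factor(cluster))
  ss_error <- sum(residuals(fit_ac)^2)
  ss_cluster <- ss_total - ss_animal - ss_error
  k <- length(unique(cluster)); m <- length(unique(animal)); n <- length(values)
  df1 <- k - 1; df2 <- n - k - m + 1
  Fv <- (ss_cluster / df1) / (ss_error / df2)
  list(F = Fv, df_between = df1, df_error = df2,
       p_value = pf(Fv, df1, df2, lower.tail = FALSE),
       ss = c(cluster = ss_cluster, animal = ss_animal, error = ss_error,
              total = ss_total))
}
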