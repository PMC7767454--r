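# Statistical layer: Spearman correlations, repeated-measures ANOVA with the
# animal fitted as the error term, and the chi-squared homogeneity test on
# per-cluster relocation counts.

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks on ties); the
#' p-value comes from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' which is the standard choice for the sample sizes (thousands of
#' relocations) this package works at. `rho = +/-1` gives p = 0.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value` and `n`. A constant vector has no
#'   defined rank correlation: both values are `NA` and a warning is issued.
#' @examples
#' spearman_rho(1:5, c(1, 3, 2, 5, 4))$rho   # 0.8
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n) stop("spearman_rho needs equal-length vectors, n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman's rho is undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Pairwise Spearman correlations of the movement variables
#'
#' All pairwise (rho, p) among distance, ROM, linearity ratio and turning
#' angle, each pair using its pairwise-complete rows.
#'
#' @param ft A `feature_table` from [build_feature_table()].
#' @return A `correlation_matrix`: list of symmetric matrices `rho`, `p` and
#'   `n` (diagonal rho = 1).
#' @export
correlation_matrix <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  vars <- c("distance", "rom", "linearity", "turning_angle")
  if (sum(complete.cases(ft[, vars])) < 3) {
    stop("correlation matrix needs at least 3 complete rows")
  }
  p <- length(vars)
  rho <- pmat <- nmat <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  diag(rho) <- 1
  diag(pmat) <- 0
  diag(nmat) <- colSums(!is.na(ft[, vars]))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      r <- spearman_rho(ft[[vars[i]]], ft[[vars[j]]])
      rho[i, j] <- rho[j, i] <- r$rho
      pmat[i, j] <- pmat[j, i] <- r$p_value
      nmat[i, j] <- nmat[j, i] <- r$n
    }
  }
  structure(list(rho = rho, p = pmat, n = nmat), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix> Spearman's rho (lower triangle: p-values)\n")
  m <- x$rho
  m[lower.tri(m)] <- x$p[lower.tri(m)]
  print(round(m, 3))
  invisible(x)
}

#' Repeated-measures one-way ANOVA with animal as the error term
#'
#' Tests whether a movement variable differs between clusters while
#' accounting for repeated measures within animal. The sequential (Type-I)
#' sum-of-squares decomposition enters the animal term first, so
#' `SS_total = SS_animal + SS_cluster + SS_error` and the cluster effect is
#' assessed against the residual:
#' `F = MS_cluster / MS_error` on `(k - 1, n - k - m + 1)` degrees of
#' freedom for k clusters and m animals.
#'
#' @param values Numeric response (one movement variable per relocation).
#' @param cluster Cluster labels, one per observation (>= 2 distinct).
#' @param animal Animal identifiers, one per observation (>= 2 distinct).
#' @return An `rm_anova`: list with `F`, `df_between`, `df_error`, `p_value`,
#'   and the sum-of-squares partition `ss` (cluster, animal, error, total).
#'   A response with zero variance gives `F = 0`, `p = 1`.
#' @export
rm_anova <- function(values, cluster, animal) {
  n <- length(values)
  stopifnot(length(cluster) == n, length(animal) == n)
  ok <- complete.cases(values, cluster, animal)
  values <- values[ok]; cluster <- factor(cluster[ok]); animal <- factor(animal[ok])
  n <- length(values)
  k <- nlevels(cluster); m <- nlevels(animal)
  if (k < 2) stop("rm_anova needs at least 2 clusters")
  if (m < 2) stop("rm_anova needs at least 2 animals")
  if (sd(values) == 0) {               # no variance at all: nothing to test
    return(structure(list(F = 0, df_between = k - 1, df_error = n - k - m + 1,
                          p_value = 1,
                          ss = c(cluster = 0, animal = 0, error = 0, total = 0)),
                     class = "rm_anova"))
  }
  fit <- lm(values ~ animal + cluster)
  tab <- anova(fit)
  ss_animal <- tab["animal", "Sum Sq"]
  ss_cluster <- tab["cluster", "Sum Sq"]
  ss_error <- tab["Residuals", "Sum Sq"]
  df_between <- tab["cluster", "Df"]
  df_error <- tab["Residuals", "Df"]
  if (sum(tab[, "Sum Sq"]) <= .Machine$double.eps * n) {
    Fval <- 0; pval <- 1
  } else {
    Fval <- (ss_cluster / df_between) / (ss_error / df_error)
    if (!is.finite(Fval)) Fval <- 0
    pval <- pf(Fval, df_between, df_error, lower.tail = FALSE)
  }
  structure(list(F = Fval, df_between = df_between, df_error = df_error,
                 p_value = pval,
                 ss = c(cluster = ss_cluster, animal = ss_animal,
                        error = ss_error,
                        total = ss_cluster + ss_animal + ss_error)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (animal as error term): F(%d, %d) = %.4g, p = %.3g\n",
              x$df_between, x$df_error, x$F, x$p_value))
  cat(sprintf("  SS: cluster %.4g, animal %.4g, error %.4g (total %.4g)\n",
              x$ss[["cluster"]], x$ss[["animal"]], x$ss[["error"]], x$ss[["total"]]))
  invisible(x)
}

#' Chi-squared test of homogeneity for relocation counts
#'
#' Tests whether relocations are spread evenly over the clusters: expected
#' counts are `total / n_categories` in every category,
#' `chi2 = sum (obs - exp)^2 / exp` on `n_categories - 1` degrees of freedom.
#'
#' @param counts Non-negative counts, length >= 2, positive total.
#' @return A `chisq_homogeneity`: list with `chi2`, `df`, `p_value`,
#'   `observed` and `expected`.
#' @examples
#' chisq_homogeneity(c(684, 2862, 2275))$chi2   # ~1309
#' @export
chisq_homogeneity <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2) stop("need at least 2 categories")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("total count must be positive")
  ht <- suppressWarnings(stats::chisq.test(counts))
  structure(list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, observed = counts,
                 expected = unname(ht$expected)),
            class = "chisq_homogeneity")
}

#' @export
print.chisq_homogeneity <- function(x, ...) {
  cat(sprintf("Chi-squared homogeneity test: chi2 = %.4g, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}
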