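#' Overall and per-cluster movement summary
#'
#' Builds the summary layer of the analysis: mean, SD, median, min and max of
#' each movement variable, overall and within each behavioural cluster, plus
#' per-animal relocation counts (overall and per cluster) and the attached
#' tests -- a repeated-measures ANOVA per variable ([rm_anova()]) and a
#' chi-squared homogeneity test on the per-cluster relocation totals
#' ([chisq_homogeneity()]).
#'
#' @param ft A `feature_table`.
#' @param labels Integer cluster labels for the *complete* rows of `ft`
#'   (aligned with [feature_matrix()]), e.g. from a relabelled
#'   `cluster_result`.
#' @return A `movement_summary`: list with
#'   `variables` (long data.frame: variable, cluster ("overall" or the
#'   cluster number), n, mean, sd, median, min, max),
#'   `relocations` (same statistics for per-animal relocation counts),
#'   `cluster_counts` (relocations per cluster), `anova` (list per variable)
#'   and `chisq`.
#' @export
cluster_summary_table <- function(ft, labels) {
  stopifnot(inherits(ft, "feature_table"))
  comp <- ft[ft$complete, , drop = FALSE]
  if (nrow(comp) == 0) stop("feature table has no complete rows")
  if (length(labels) != nrow(comp)) {
    stop("labels must have one entry per complete feature row")
  }
  vars <- c("distance", "rom", "linearity", "turning_angle")
  ks <- sort(unique(labels))

  stat_row <- function(v, cl, x) {
    x <- x[!is.na(x)]
    data.frame(variable = v, cluster = cl, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) sd(x) else 0, median = median(x),
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  }
  var_rows <- list()
  for (v in vars) {
    var_rows[[length(var_rows) + 1]] <- stat_row(v, "overall", comp[[v]])
    for (k in ks) {
      var_rows[[length(var_rows) + 1]] <-
        stat_row(v, as.character(k), comp[[v]][labels == k])
    }
  }
  variables <- do.call(rbind, c(var_rows, list(make.row.names = FALSE)))

  counts_overall <- table(comp$animal_id)
  rel_rows <- list(stat_row("relocations", "overall", as.numeric(counts_overall)))
  for (k in ks) {
    ck <- table(comp$animal_id[labels == k])
    rel_rows[[length(rel_rows) + 1]] <-
      stat_row("relocations", as.character(k), as.numeric(ck))
  }
  relocations <- do.call(rbind, c(rel_rows, list(make.row.names = FALSE)))

  cluster_counts <- vapply(ks, function(k) sum(labels == k), numeric(1))
  names(cluster_counts) <- as.character(ks)

  anovas <- if (length(ks) >= 2 && length(unique(comp$animal_id)) >= 2) {
    setNames(lapply(vars, function(v) {
      rm_anova(comp[[v]], labels, comp$animal_id)
    }), vars)
  } else NULL
  chisq <- if (length(ks) >= 2) chisq_homogeneity(cluster_counts) else NULL

  structure(list(variables = variables, relocations = relocations,
                 cluster_counts = cluster_counts, anova = anovas,
                 chisq = chisq),
            class = "movement_summary")
}

#' @export
print.movement_summary <- function(x, digits = 3, ...) {
  fmt <- function(df) {
    data.frame(
      variable = df$variable, cluster = df$cluster, n = df$n,
      `mean(sd)` = sprintf("%.*g (%.*g)", digits, df$mean, digits, df$sd),
      `median(min,max)` = sprintf("%.*g (%.*g, %.*g)", digits, df$median,
                                  digits, df$min, digits, df$max),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  cat("Movement pattern summary (overall and per cluster)\n\n")
  print(fmt(x$relocations), row.names = FALSE)
  cat("\n")
  print(fmt(x$variables), row.names = FALSE)
  if (!is.null(x$chisq)) {
    cat(sprintf("\nRelocations between clusters: chi2 = %.4g, df = %d, p = %.3g\n",
                x$chisq$chi2, x$chisq$df, x$chisq$p_value))
  }
  if (!is.null(x$anova)) {
    for (v in names(x$anova)) {
      a <- x$anova[[v]]
      cat(sprintf("%s: F(%d, %d) = %.4g, p = %.3g\n",
                  v, a$df_between, a$df_error, a$F, a$p_value))
    }
  }
  invisible(x)
}
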