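test_that("Spearman's rho matches rank arithmetic and the reference implementation", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, (1:10)^3)$p_value, 0)
  expect_equal(spearman_rho(1:10, -(1:10))$rho, -1)
  r <- spearman_rho(1:5, c(1, 3, 2, 5, 4))
  expect_equal(r$rho, 0.8)                               # 1 - 6*4/(5*24)
  expect_equal(r$p_value, 2 * pt(-0.8 * sqrt(3 / (1 - 0.64)), 3), tolerance = 1e-12)
  set.seed(41)
  x <- rnorm(50); y <- rnorm(50) + 0.5 * x
  expect_equal(spearman_rho(x, y)$rho,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  # invariance under strictly monotone transforms of either argument
  expect_equal(spearman_rho(exp(x), y)$rho, spearman_rho(x, y)$rho)
  expect_equal(spearman_rho(x, qlogis(plogis(y)))$rho, spearman_rho(x, y)$rho)
  expect_warning(out <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
  expect_error(spearman_rho(1:2, 1:2), "n >= 3")
})

test_that("the correlation matrix is symmetric with unit diagonal", {
  sim <- small_sim(seed = 42, n_animals = 3, days = 1)
  ft <- build_feature_table(sim$trajectories, window = 5)
  cm <- correlation_matrix(ft)
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, 4))
  expect_true(all(abs(cm$rho) <= 1, na.rm = TRUE))
  expect_true(all(cm$p >= 0 & cm$p <= 1, na.rm = TRUE))
  # a duplicated column correlates perfectly with itself
  ft2 <- ft
  ft2$turning_angle <- ft2$rom
  expect_equal(correlation_matrix(ft2)$rho["rom", "turning_angle"], 1)
  # movement speed tracks distance more closely than the turning angle does
  expect_gt(cm$rho["rom", "distance"], abs(cm$rho["turning_angle", "distance"]))
})

test_that("repeated-measures ANOVA reproduces the explicit SS decomposition", {
  set.seed(43)
  for (rep in 1:5) {
    n <- 60
    animal <- sample(letters[1:5], n, replace = TRUE)
    cluster <- sample(1:3, n, replace = TRUE)
    values <- rnorm(n) + as.numeric(factor(animal)) * 0.5 + (cluster == 2) * 0.8
    got <- rm_anova(values, cluster, animal)
    want <- direct_rm_anova(values, cluster, animal)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    expect_equal(got$ss, want$ss, tolerance = 1e-8)
    # bookkeeping invariants
    expect_equal(got$df_between + got$df_error, n - 1 - (5 - 1))
    expect_equal(got$ss[["total"]], sum((values - mean(values))^2), tolerance = 1e-8)
    expect_true(all(got$ss >= -1e-10))
  }
  # three clusters -> 2 numerator degrees of freedom
  expect_equal(rm_anova(rnorm(30), rep(1:3, 10), rep(1:2, 15))$df_between, 2)
  # no cluster effect possible: identical values
  flat <- rm_anova(rep(2.5, 20), rep(1:2, 10), rep(letters[1:4], 5))
  expect_equal(flat$F, 0)
  expect_equal(flat$p_value, 1)
  # identical cluster means in a balanced layout with residual noise: F = 0
  v <- c(1, 3, 1, 3)
  cl <- c(1, 2, 2, 1)
  an <- c("a", "a", "b", "b")
  expect_equal(rm_anova(v, cl, an)$F, 0, tolerance = 1e-12)
  expect_error(rm_anova(rnorm(10), rep(1, 10), rep(1:2, 5)), "2 clusters")
  expect_error(rm_anova(rnorm(10), rep(1:2, 5), rep("a", 10)), "2 animals")
})

test_that("chi-squared homogeneity matches the textbook formula", {
  eq <- chisq_homogeneity(c(100, 100, 100))
  expect_equal(eq$chi2, 0)
  expect_equal(eq$df, 2)
  expect_equal(eq$p_value, 1)
  expect_equal(chisq_homogeneity(c(10, 0))$chi2, 10)     # (10-5)^2/5 + (0-5)^2/5
  expect_equal(chisq_homogeneity(c(10, 0))$df, 1)
  set.seed(44)
  for (rep in 1:10) {
    counts <- rpois(sample(2:6, 1), lambda = 40)
    if (sum(counts) == 0) next
    got <- chisq_homogeneity(counts)
    expect_equal(got$chi2, direct_chisq(counts), tolerance = 1e-10)
    expect_equal(got$df, length(counts) - 1)
    expect_equal(got$p_value, pchisq(got$chi2, got$df, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(chisq_homogeneity(c(-1, 5)), "non-negative")
  expect_error(chisq_homogeneity(5), "2 categories")
})

test_that("the movement summary table conserves counts and collapses correctly", {
  sim <- small_sim(seed = 45, n_animals = 4, days = 1)
  ft <- build_feature_table(sim$trajectories, window = 5)
  n_comp <- sum(ft$complete)
  set.seed(45)
  labels <- sample(1:3, n_comp, replace = TRUE)
  ms <- cluster_summary_table(ft, labels)
  expect_equal(sum(ms$cluster_counts), n_comp)
  v <- ms$variables
  expect_true(all(v$mean >= v$min - 1e-12 & v$mean <= v$max + 1e-12))
  overall_n <- v$n[v$variable == "rom" & v$cluster == "overall"]
  expect_equal(sum(v$n[v$variable == "rom" & v$cluster != "overall"]), overall_n)
  # a single cluster reproduces the overall block
  ms1 <- cluster_summary_table(ft, rep(1L, n_comp))
  v1 <- ms1$variables
  for (vr in unique(v1$variable)) {
    expect_equal(v1[v1$variable == vr & v1$cluster == "1", -(1:2)],
                 v1[v1$variable == vr & v1$cluster == "overall", -(1:2)],
                 ignore_attr = TRUE)
  }
  expect_null(ms1$chisq)
})
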