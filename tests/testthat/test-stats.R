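test_that("two-group tests behave at the identity and under huge effects", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  tt <- compare_two_groups(x, x, method = "t")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  set.seed(4)
  a <- rnorm(200); b <- rnorm(200, 3)
  expect_lt(compare_two_groups(a, b, method = "t")$p_value, 1e-10)
  expect_lt(compare_two_groups(a, b, method = "wilcoxon")$p_value, 1e-10)
  expect_equal(compare_two_groups(a, b, method = "t")$direction, -1)
  expect_error(compare_two_groups(1, a), class = "paravec_validation_error")
})

test_that("Welch t matches the closed-form oracle", {
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(sample(5:40, 1), 0, 1)
    y <- rnorm(sample(5:40, 1), 0.4, 1.7)
    got <- compare_two_groups(x, y, method = "t")
    exp_ <- welch_oracle(x, y)
    expect_equal(got$statistic, exp_$statistic, tolerance = 1e-12)
    expect_equal(got$p_value, exp_$p, tolerance = 1e-12)
  }
})

test_that("Wilcoxon matches enumeration (exact) and the normal formula", {
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(sample(4:6, 1)); y <- rnorm(sample(4:6, 1))
    got <- compare_two_groups(x, y, method = "wilcoxon")
    exp_ <- wilcox_exact_oracle(x, y)
    expect_equal(got$statistic, exp_$statistic)
    expect_equal(got$p_value, exp_$p, tolerance = 1e-12)
  }
  for (s in 1:10) {
    set.seed(100 + s)
    x <- sample(1:15, 40, replace = TRUE)  # ties force the approximation
    y <- sample(3:18, 35, replace = TRUE)
    got <- compare_two_groups(x, y, method = "wilcoxon")
    exp_ <- wilcox_normal_oracle(x, y)
    expect_equal(got$p_value, exp_$p, tolerance = 1e-12)
  }
})

test_that("k-group testing: identical groups, separated groups, Holm", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  res <- compare_k_groups(g)
  expect_lt(res$statistic, 1e-10)
  expect_true(all(res$pairwise_p[upper.tri(res$pairwise_p)] == 1))
  # all groups share a letter when nothing is significant
  expect_equal(length(unique(res$letters)), 1)

  set.seed(9)
  far <- list(a = rnorm(30, 0), b = rnorm(30, 10), c = rnorm(30, 20))
  res2 <- compare_k_groups(far)
  expect_lt(res2$p_value, 1e-10)
  expect_true(all(res2$pairwise_p[upper.tri(res2$pairwise_p)] < 0.05))
  expect_equal(sort(unname(res2$letters)), c("a", "b", "c"))

  # Kruskal-Wallis statistic matches the rank formula with tie correction
  set.seed(10)
  tied <- list(a = sample(1:6, 25, TRUE), b = sample(2:8, 30, TRUE),
               c = sample(1:9, 20, TRUE))
  got <- compare_k_groups(tied)
  exp_ <- kruskal_oracle(tied)
  expect_equal(got$statistic, exp_$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, exp_$p, tolerance = 1e-12)

  # Holm adjustment: matches definition, never decreases a p-value
  set.seed(11)
  p <- runif(7)^2
  expect_equal(stats::p.adjust(p, "holm"), holm_oracle(p),
               tolerance = 1e-15)
  expect_true(all(stats::p.adjust(p, "holm") >= p))
  expect_error(compare_k_groups(list(a = 1, b = c(1, 2))),
               class = "paravec_validation_error")
})

test_that("normality check is calibrated and bounded", {
  p_norm <- sapply(1:50, function(s) {
    set.seed(s); normality_check(rnorm(500))$p_value
  })
  expect_gte(mean(p_norm > 0.05), 0.9)
  p_exp <- sapply(1:50, function(s) {
    set.seed(s); normality_check(rexp(500))$p_value
  })
  expect_gte(mean(p_exp < 0.05), 0.98)
  set.seed(1)
  res <- normality_check(rnorm(100))
  expect_lte(res$statistic, 1)
  expect_false(res$subsampled)
  big <- normality_check(rnorm(6000), seed = 2)
  expect_true(big$subsampled)
  expect_equal(big$n, 5000)
  expect_error(normality_check(rep(1, 10)),
               class = "paravec_validation_error")
})

test_that("trend fits recover exact lines and nonlinear signal", {
  x <- seq(0, 120, length.out = 60)
  flat <- fit_trend(x, rep(5, 60))
  expect_lte(flat$linear$r_squared, 1e-10)
  expect_lte(flat$smooth$deviance_explained, 1e-8)

  line <- fit_trend(x, 2 * x)
  expect_equal(line$linear$r_squared, 1, tolerance = 1e-10)
  expect_lt(line$linear$p_value, 1e-10)

  set.seed(12)
  x2 <- runif(500, 0, 120)
  y2 <- sin(x2 / 20) + rnorm(500, 0, 0.1)
  tr <- fit_trend(x2, y2)
  expect_gt(tr$smooth$deviance_explained, tr$linear$r_squared)
  expect_lt(tr$smooth$p_value, 1e-6)

  expect_warning(fit_trend(rep(c(1, 2, 3), 5), rnorm(15)), "unique")
  expect_error(fit_trend(1:5, 1:5), class = "paravec_validation_error")
})

test_that("the full analysis report is complete and deterministic", {
  sim <- small_sim(seed = 33, individuals = 5, n_features = 80,
                   depth = 1500, diet_effect = 2)
  cen <- sim_centroids(sim)
  vecs <- all_pair_vectors(cen, sim$diets)
  cmp <- enumerate_comparisons(vecs, sim$tree)
  q <- build_quartets(cen, sim$diets, sim$tree)
  rep1 <- run_analysis(cmp, vecs, sim$tree, q)
  rep2 <- run_analysis(cmp, vecs, sim$tree, q)
  expect_identical(rep1$table, rep2$table)
  expect_true(all(c("quartet", "lengths", "trend") %in%
                    rep1$table$section))
  expect_true(all(rep1$table$p >= 0 & rep1$table$p <= 1, na.rm = TRUE))
  # group means in the report are reproducible from the comparison table
  gm <- rep1$group_means
  for (r in seq_len(nrow(gm))) {
    expect_equal(gm$angle[r],
                 mean(cmp$angle[cmp$category == gm$category[r]],
                      na.rm = TRUE))
  }
})
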