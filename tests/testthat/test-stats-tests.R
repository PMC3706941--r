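test_that("Kruskal-Wallis matches the base-R implementation and handles ties", {
  set.seed(1)
  for (i in 1:20) {
    values <- round(rnorm(15), sample(0:2, 1))  # induce occasional ties
    groups <- sample(rep(1:3, 5))
    res <- kruskal_wallis(values, groups)
    ref <- kruskal.test(values, factor(groups))
    if (is.nan(ref$statistic)) next
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
  # all-tied input: H = 0, p = 1
  allt <- kruskal_wallis(rep(5, 9), rep(1:3, 3))
  expect_equal(allt$statistic, 0)
  expect_equal(allt$p_value, 1)
  expect_error(kruskal_wallis(1:4, c(1, 1, 1, 1)), "groups")
})

test_that("exact Kruskal-Wallis p equals the permutation tail probability", {
  values <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  groups <- rep(1:3, each = 3)
  res <- kruskal_wallis(values, groups, exact = TRUE)
  # perfect separation of 3/3/3 ranks: 6^4 / 9! orderings reach max H
  expect_equal(res$statistic, 7.2, tolerance = 1e-12)
  p_mc <- oracle_kw_perm_p(values, factor(groups), res$statistic, seed = 2)
  expect_lt(abs(res$p_value - p_mc), 0.0015)  # Monte-Carlo error bound
  expect_equal(res$p_value, 1296 / 362880, tolerance = 1e-12)
  expect_lt(res$p_value, 0.01)  # reachable significance at tiny n
})

test_that("pooled t-test matches the explicit-sum formula and t.test", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  res <- two_group_t_test(c(x, y), rep(1:2, each = 3))
  expect_equal(res$statistic, oracle_pooled_t(x, y), tolerance = 1e-12)
  ref <- t.test(y, x, var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- two_group_t_test(rep(c(1, 2, 3), 2), rep(1:2, each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  const <- two_group_t_test(rep(3, 6), rep(1:2, each = 3))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
  # zero variance, unequal means: p = 0 with the degenerate flag
  deg <- two_group_t_test(c(1, 1, 1, 2, 2, 2), rep(1:2, each = 3))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)
})

test_that("one-way ANOVA matches explicit sums of squares and aov", {
  values <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  groups <- rep(1:3, each = 3)
  res <- one_way_anova_bonferroni(values, groups, alpha = 0.01, n_tests = 1)
  expect_equal(res$statistic, oracle_anova_f(values, groups), tolerance = 1e-12)
  ref <- anova(aov(values ~ factor(groups)))
  expect_equal(res$statistic, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-12)
  # Bonferroni: the call threshold is alpha / n_tests
  many <- one_way_anova_bonferroni(values, groups, alpha = 0.01, n_tests = 1e6)
  expect_false(many$significant)
  # null behaviour: equal group means, noise only -> rarely significant
  set.seed(3)
  fps <- replicate(200, {
    one_way_anova_bonferroni(rnorm(9), groups, alpha = 0.05, n_tests = 1)$significant
  })
  expect_lt(mean(fps), 0.12)
})

test_that("BH q-values agree with the hand-computed step-up and p.adjust", {
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  set.seed(9)
  p <- runif(50)
  expect_equal(benjamini_hochberg(p), p.adjust(p, "BH"), tolerance = 1e-12)
  # monotone non-decreasing in p-rank
  q <- benjamini_hochberg(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("hypergeometric enrichment matches direct summation and phyper", {
  universe <- sprintf("g%02d", 1:20)
  ann <- data.frame(gene_id = universe[1:5], category = "cat1")
  study <- c(universe[1:4], universe[20])
  res <- hypergeometric_enrichment(study, universe, ann, threshold = 0.1)
  expect_equal(res$overlap, 4)
  expect_equal(res$p_value, oracle_hyper_tail(4, 5, 20, 5), tolerance = 1e-12)
  expect_equal(res$p_value,
               phyper(3, 5, 15, 5, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(res$enriched)
  # category covering the whole universe: certain overlap, p = 1
  ann_all <- data.frame(gene_id = universe, category = "all")
  res_all <- hypergeometric_enrichment(study, universe, ann_all)
  expect_equal(res_all$p_value, 1)
  expect_error(hypergeometric_enrichment(c("zz"), universe, ann), "universe")
})
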