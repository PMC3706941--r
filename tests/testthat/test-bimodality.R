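test_that("bimodality coefficient matches its analytic benchmarks", {
  set.seed(101)
  b_unif <- bimodality_coefficient(runif(10000))
  expect_equal(as.numeric(b_unif), 5 / 9, tolerance = 0.02 / (5 / 9))
  b_norm <- bimodality_coefficient(rnorm(10000))
  expect_equal(as.numeric(b_norm), 1 / 3, tolerance = 0.02 / (1 / 3))
  expect_false(attr(b_norm, "bimodal"))
  # balanced two-point mass is maximally bimodal
  b_two <- bimodality_coefficient(rep(c(-3, 3), 500))
  expect_gt(as.numeric(b_two), 0.9)
  expect_true(attr(b_two, "bimodal"))
})

test_that("bimodality coefficient uses bias-corrected sample moments", {
  skip_if_not_installed("e1071")
  set.seed(5)
  x <- rgamma(200, 2)
  n <- length(x)
  g1 <- e1071::skewness(x, type = 2)
  g2 <- e1071::kurtosis(x, type = 2)
  expected <- (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  expect_equal(as.numeric(bimodality_coefficient(x)), expected, tolerance = 1e-12)
})

test_that("degenerate inputs are reported not-bimodal with a warning", {
  expect_warning(b <- bimodality_coefficient(c(1, 2, 3)), "undefined")
  expect_true(is.na(b))
  expect_false(attr(b, "bimodal"))
  expect_warning(b2 <- bimodality_coefficient(rep(2, 10)), "undefined")
  expect_false(attr(b2, "bimodal"))
})

test_that("the k-means sweep recovers the planted low bimodal cluster", {
  d <- generate_dataset(synthetic_spec(), seed = 31)
  part <- unimodal_filter(d$expr, k_max = 15, seed = 2)
  expect_true(part$converged)
  low <- d$truth$gene_id[d$truth$class == "bimodal_low"]
  in_bimodal <- part$assignment$gene_id[part$assignment$cluster == part$bimodal_cluster]
  expect_gte(mean(low %in% in_bimodal), 0.95)
  # the flagged cluster has the minimal mean intensity
  flagged <- part$clusters[part$clusters$cluster == part$bimodal_cluster, ]
  expect_equal(flagged$mean_intensity, min(part$clusters$mean_intensity))
  # partition property: unimodal set and bimodal cluster tile the genes
  expect_setequal(c(part$unimodal_set, in_bimodal), d$expr$gene_id)
  expect_length(intersect(part$unimodal_set, in_bimodal), 0)
})

test_that("all-Gaussian data gives a non-convergence flag and keeps all genes", {
  sp <- synthetic_spec(n_vineyards = 4, n_constitutive = 0, n_marker_up = 0,
                       n_marker_down = 0, n_plastic = 0, n_year_effect = 0,
                       n_bimodal_low = 0, n_background = 200)
  d <- generate_dataset(sp, seed = 17)
  part <- unimodal_filter(d$expr, k_max = 6, seed = 2)
  expect_false(part$converged)
  expect_setequal(part$unimodal_set, d$expr$gene_id)
})

test_that("the sweep is deterministic under a fixed seed", {
  d <- generate_dataset(synthetic_spec(n_vineyards = 4, n_background = 100,
                                       n_bimodal_low = 100, n_constitutive = 20,
                                       n_marker_up = 20, n_marker_down = 20,
                                       n_plastic = 20, n_year_effect = 0),
                        seed = 3)
  p1 <- unimodal_filter(d$expr, k_max = 8, seed = 10)
  p2 <- unimodal_filter(d$expr, k_max = 8, seed = 10)
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(p1$k, p2$k)
})

test_that("adding well-separated two-point genes cannot hide the bimodal cluster", {
  sp <- synthetic_spec(n_vineyards = 4, n_constitutive = 0, n_marker_up = 0,
                       n_marker_down = 0, n_plastic = 0, n_year_effect = 0,
                       n_bimodal_low = 0, n_background = 150)
  base <- generate_dataset(sp, seed = 23)
  n_add <- 60
  set.seed(24)
  nms <- names(base$expr)[-1]
  low <- 2.5 + 2.5 * matrix(rbinom(n_add * length(nms), 1, 0.5), n_add) +
    matrix(rnorm(n_add * length(nms), 0, 0.4), n_add)
  added <- make_expr(low, gene_ids = sprintf("ADD%03d", seq_len(n_add)),
                     sample_names = nms)
  combined <- as_expr(dplyr::bind_rows(tibble::as_tibble(base$expr),
                                       tibble::as_tibble(added)))
  part <- unimodal_filter(combined, k_max = 10, seed = 5)
  in_bimodal <- part$assignment$gene_id[part$assignment$cluster == part$bimodal_cluster]
  expect_gte(length(intersect(in_bimodal, added$gene_id)), 0.9 * n_add)
})
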