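test_that("generation is deterministic under a fixed seed", {
  sp <- synthetic_spec(n_vineyards = 3, n_constitutive = 10, n_marker_up = 10,
                       n_marker_down = 10, n_plastic = 10, n_year_effect = 0,
                       n_bimodal_low = 10, n_background = 10)
  d1 <- generate_dataset(sp, seed = 99)
  d2 <- generate_dataset(sp, seed = 99)
  expect_identical(d1$expr, d2$expr)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(sp, seed = 100)
  expect_false(identical(d1$expr, d3$expr))
})

test_that("truth-table class counts match the spec and labels are unique", {
  sp <- synthetic_spec(n_vineyards = 2, n_constitutive = 3, n_marker_up = 4,
                       n_marker_down = 5, n_plastic = 6, n_year_effect = 7,
                       n_bimodal_low = 8, n_background = 9)
  d <- generate_dataset(sp, seed = 1)
  counts <- table(d$truth$class)
  expect_equal(unname(counts[c("constitutive", "marker_up", "marker_down",
                               "plastic", "year_effect", "bimodal_low",
                               "background")]),
               c(3L, 4L, 5L, 6L, 7L, 8L, 9L), ignore_attr = TRUE)
  expect_equal(anyDuplicated(d$truth$gene_id), 0L)
  expect_equal(d$truth$gene_id, d$expr$gene_id)
})

test_that("noiseless degenerate spec gives constant genes", {
  sp <- synthetic_spec(n_vineyards = 2, n_constitutive = 0, n_marker_up = 0,
                       n_marker_down = 0, n_plastic = 0, n_year_effect = 0,
                       n_bimodal_low = 0, n_background = 5,
                       baseline_sd = 0.7, replicate_noise_sd = 0)
  d <- generate_dataset(sp, seed = 5)
  m <- expr_matrix(d$expr)
  expect_true(all(apply(m, 1, function(v) diff(range(v))) == 0))
})

test_that("class-conditional expectations follow the generative formulas", {
  sp <- synthetic_spec(n_vineyards = 11, n_constitutive = 0, n_marker_up = 200,
                       n_marker_down = 200, n_plastic = 0, n_year_effect = 0,
                       n_bimodal_low = 0, n_background = 0,
                       stage_effect = 2, replicate_noise_sd = 0.3)
  d <- generate_dataset(sp, seed = 21)
  m <- expr_matrix(d$expr)
  info <- expr_samples(d$expr)
  s1 <- rowMeans(m[, info$stage == 1])
  s3 <- rowMeans(m[, info$stage == 3])
  up <- d$truth$class == "marker_up"
  # expected stage-3 minus stage-1 difference: +/- stage_effect * 2
  expect_equal(mean(s3[up] - s1[up]), 4, tolerance = 0.02)
  expect_equal(mean(s3[!up] - s1[!up]), -4, tolerance = 0.02)
})

test_that("replicate noise reproduces its specified moments", {
  sp <- synthetic_spec(n_vineyards = 11, n_constitutive = 0, n_marker_up = 0,
                       n_marker_down = 0, n_plastic = 0, n_year_effect = 0,
                       n_bimodal_low = 0, n_background = 150,
                       replicate_noise_sd = 0.5)
  d <- generate_dataset(sp, seed = 8)
  m <- expr_matrix(d$expr)  # 150 x 99 -> ~15,000 noise draws
  resid <- m - rowMeans(m)
  n <- ncol(m)
  pooled_sd <- sqrt(sum(resid^2) / (nrow(m) * (n - 1)))
  expect_gte(pooled_sd, 0.48)
  expect_lte(pooled_sd, 0.52)
})

test_that("default spec yields a bimodal pooled intensity histogram", {
  d <- generate_dataset(synthetic_spec(), seed = 13)
  b <- bimodality_coefficient(as.vector(expr_matrix(d$expr)))
  expect_gt(as.numeric(b), bimodality_threshold())
})

test_that("empty designs are rejected", {
  expect_error(synthetic_spec(n_vineyards = 0), ">= 1")
  sp <- synthetic_spec(n_constitutive = 0, n_marker_up = 0, n_marker_down = 0,
                       n_plastic = 0, n_year_effect = 0, n_bimodal_low = 0,
                       n_background = 0)
  expect_error(generate_dataset(sp, seed = 1), "Zero total genes")
})
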