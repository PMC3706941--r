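sam_toy <- function(seed = 4, n_genes = 40, shift_genes = 4, shift = 3) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 6), n_genes, 6)
  m[seq_len(shift_genes), 4:6] <- m[seq_len(shift_genes), 4:6] + shift
  make_expr(m, sample_names = c("AM081A", "AM081B", "AM081C",
                                "CS081A", "CS081B", "CS081C"))
}

test_that("two-class d matches the explicit formula on a 3v3 toy", {
  e <- sam_toy()
  fit <- sam(e, "vineyard", fdr_target = 0.05, n_perms = 100, seed = 1)
  x <- expr_matrix(e)
  labels <- expr_samples(e)$vineyard
  rs <- oracle_sam_rs(x, labels)
  expect_equal(tidy(fit)$r, unname(rs$r), tolerance = 1e-12)
  expect_equal(tidy(fit)$s, unname(rs$s), tolerance = 1e-12)
  expect_equal(tidy(fit)$d, unname(rs$r / (rs$s + fit$s0)), tolerance = 1e-12)
  # all 20 balanced assignments were enumerated
  expect_true(fit$enumerated)
  expect_equal(fit$n_perms_used, 20)
})

test_that("expected order statistics and FDR match a full enumeration oracle", {
  e <- sam_toy()
  fit <- sam(e, "vineyard", fdr_target = 0.05, n_perms = 100, seed = 1)
  x <- expr_matrix(e)
  # oracle: every choose(6,3) assignment of columns to the first class
  sel <- utils::combn(6, 3)
  d_perm <- sapply(seq_len(ncol(sel)), function(j) {
    lab <- rep("b", 6); lab[sel[, j]] <- "a"
    rs <- oracle_sam_rs(x, lab)
    sort(rs$r / (rs$s + fit$s0))
  })
  dbar_oracle <- rowMeans(d_perm)
  expect_equal(sort(tidy(fit)$dbar), dbar_oracle, tolerance = 1e-10)
  # FDR at each tabulated delta against the oracle count
  qs <- quantile(d_perm, c(0.25, 0.75))
  pi0_oracle <- min(1, sum(tidy(fit)$d >= qs[1] & tidy(fit)$d <= qs[2]) /
                      (0.5 * nrow(x)))
  expect_equal(fit$pi0, pi0_oracle, tolerance = 1e-12)
  d_sorted <- sort(tidy(fit)$d)
  for (row in sample(seq_len(nrow(fit$delta_table)), 5)) {
    delta <- fit$delta_table$delta[row]
    dev <- d_sorted - dbar_oracle
    up <- which(dev >= delta - 1e-9 & d_sorted >= 0)
    lo <- which(dev <= -(delta - 1e-9) & d_sorted <= 0)
    cuthi <- if (length(up)) d_sorted[min(up)] else Inf
    cutlo <- if (length(lo)) d_sorted[max(lo)] else -Inf
    called <- sum(d_sorted >= cuthi - 1e-9) + sum(d_sorted <= cutlo + 1e-9)
    fp <- apply(d_perm, 2,
                function(dp) sum(dp >= cuthi - 1e-9) + sum(dp <= cutlo + 1e-9))
    fdr_mean_oracle <- if (called == 0) 0 else min(1, mean(fp) * pi0_oracle / called)
    fdr_median_oracle <- if (called == 0) 0 else min(1, median(fp) * pi0_oracle / called)
    expect_equal(fit$delta_table$fdr[row], fdr_mean_oracle, tolerance = 1e-10)
    expect_equal(fit$delta_table$fdr_median[row], fdr_median_oracle, tolerance = 1e-10)
    expect_equal(fit$delta_table$n_called[row], called)
  }
})

test_that("planted shifts are called and the called-set size shrinks with delta", {
  # with full enumeration the identity relabelling bounds the mean
  # false-positive count below by called/n_perms, so the reachable FDR floor
  # here is ~pi0/20; test at an operating point above it
  e <- sam_toy(shift = 4)
  fit <- sam(e, "vineyard", fdr_target = 0.1, n_perms = 100, seed = 1)
  expect_true(all(sprintf("G%03d", 1:4) %in% fit$significant))
  expect_true(all(diff(fit$delta_table$n_called) <= 0))
  expect_gte(fit$fdr, 0)
})

test_that("pure-noise labels give an empty called set at FDR 0.1%", {
  empty <- vapply(1:20, function(s) {
    set.seed(s + 500)
    m <- matrix(rnorm(300 * 6), 300, 6)
    e <- make_expr(m, sample_names = c("AM081A", "AM081B", "AM081C",
                                       "CS081A", "CS081B", "CS081C"))
    fit <- sam(e, "vineyard", fdr_target = 0.001, n_perms = 20, seed = s)
    length(fit$significant) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.95)
})

test_that("multiclass d reduces to |two-class d| for two groups", {
  e <- sam_toy()
  f2 <- sam(e, "vineyard", mode = "two_class", fdr_target = 0.05,
            n_perms = 50, seed = 1, s0 = 0.2)
  fm <- sam(e, "vineyard", mode = "multiclass", fdr_target = 0.05,
            n_perms = 50, seed = 1, s0 = 0.2)
  expect_equal(tidy(fm)$d, abs(tidy(f2)$d), tolerance = 1e-10)
})

test_that("SAM is invariant to consistent column permutation and seeded", {
  e <- sam_toy()
  fit1 <- sam(e, "vineyard", fdr_target = 0.05, n_perms = 100, seed = 7)
  fit2 <- sam(e, "vineyard", fdr_target = 0.05, n_perms = 100, seed = 7)
  expect_identical(tidy(fit1), tidy(fit2))
  # shuffle sample columns (labels derived from names follow automatically)
  perm <- c(4, 1, 5, 2, 6, 3)
  shuffled <- expr_subset(e, samples = names(e)[-1][perm])
  fit3 <- sam(shuffled, "vineyard", fdr_target = 0.05, n_perms = 100, seed = 7)
  expect_equal(tidy(fit3)$d, tidy(fit1)$d, tolerance = 1e-12)
  expect_setequal(fit3$significant, fit1$significant)
})

test_that("SAM null FDR estimate tracks the realized false-positive rate", {
  # planted-signal matrix: FDR estimate within a factor of 2 of the realized
  # false-positive proportion at the chosen operating point
  set.seed(42)
  n_genes <- 400
  m <- matrix(rnorm(n_genes * 6), n_genes, 6)
  true_idx <- 1:60
  m[true_idx, 4:6] <- m[true_idx, 4:6] + 2.5
  e <- make_expr(m, sample_names = c("AM081A", "AM081B", "AM081C",
                                     "CS081A", "CS081B", "CS081C"))
  fit <- sam(e, "vineyard", fdr_target = 0.15, n_perms = 20, seed = 3)
  called_idx <- match(fit$significant, e$gene_id)
  realized <- mean(!(called_idx %in% true_idx))
  expect_lte(abs(fit$fdr - realized), pmax(0.15, 2 * realized))
})
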