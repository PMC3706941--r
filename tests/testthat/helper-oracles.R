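# Small fixture builders and independent brute-force oracles used across the
# suite. Oracles are written from the defining formulas, independent of the
# package implementation paths they check.

make_expr <- function(m, gene_ids = sprintf("G%03d", seq_len(nrow(m))),
                      sample_names, scale = "log2") {
  colnames(m) <- sample_names
  df <- dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                         tibble::as_tibble(m, .name_repair = "minimal"))
  plasticome::as_expr(df, scale = scale)
}

# sample names for a full factorial design
design_names <- function(vineyards, year = "08", stages = 1:3, reps = c("A", "B", "C")) {
  g <- expand.grid(rep = reps, stage = stages, vy = vineyards,
                   stringsAsFactors = FALSE)
  paste0(g$vy, year, g$stage, g$rep)
}

# Pearson correlation by explicit sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# one-way ANOVA F by explicit sums of squares
oracle_anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (l in levels(groups)) {
    v <- values[groups == l]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  (ssb / (nlevels(groups) - 1)) / (ssw / (length(values) - nlevels(groups)))
}

# pooled-variance two-sample t by explicit sums
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Monte-Carlo permutation p for Kruskal-Wallis H (independent of the
# package's enumeration): sample random reassignments of values to groups.
oracle_kw_perm_p <- function(values, groups, h_obs, n_draws = 40000, seed = 1) {
  set.seed(seed)
  stat <- function(v) {
    r <- rank(v)
    n <- length(v)
    12 / (n * (n + 1)) *
      sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  }
  hs <- replicate(n_draws, stat(sample(values)))
  mean(hs >= h_obs - 1e-12)
}

# SAM two-class building blocks by explicit formulas (no fudge factor)
oracle_sam_rs <- function(x, labels) {
  l <- as.factor(labels)
  a <- x[, l == levels(l)[1], drop = FALSE]
  b <- x[, l == levels(l)[2], drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  r <- rowMeans(b) - rowMeans(a)
  pooled <- (apply(a, 1, function(v) sum((v - mean(v))^2)) +
               apply(b, 1, function(v) sum((v - mean(v))^2))) / (n1 + n2 - 2)
  s <- sqrt((1 / n1 + 1 / n2) * pooled)
  list(r = unname(r), s = unname(s))
}

# hypergeometric upper tail by direct combinatorial summation
oracle_hyper_tail <- function(k, K, N, n) {
  total <- choose(N, n)
  sum(sapply(k:min(K, n), function(i) choose(K, i) * choose(N - K, n - i))) / total
}

# naive agglomerative clustering oracle (average or complete linkage):
# repeatedly merge the closest pair, recording heights
oracle_agglomerate <- function(d, linkage = "average") {
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  dist_between <- function(a, b) {
    vals <- d[a, b]
    if (linkage == "average") mean(vals) else max(vals)
  }
  while (length(active) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i < j) {
        dd <- dist_between(active[[i]], active[[j]])
        if (dd < best_d - 1e-12) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- c(active[-best], list(merged))
  }
  heights
}
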