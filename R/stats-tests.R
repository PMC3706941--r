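#' Tie-corrected Kruskal-Wallis rank test
#'
#' `H = [ 12/(N(N+1)) * sum(n_i * rbar_i^2) - 3(N+1) ] / (1 - sum(t^3 - t)/(N^3 - N))`
#' with `t` the tie-group sizes; p-value from the chi-square approximation
#' with (groups - 1) degrees of freedom, or by exact enumeration of group
#' assignments for small samples (`exact = TRUE`).
#'
#' @param values Numeric vector.
#' @param groups Group label per value (>= 2 groups, each non-empty).
#' @param exact If `TRUE`, the p-value is the exact permutation tail
#'   probability `P(H >= H_obs)` over all distinct assignments of values to
#'   groups (feasible for ~10 values).
#' @return Tibble: `statistic` (H), `df`, `p_value`, `method`.
#' @export
kruskal_wallis <- function(values, groups, exact = FALSE) {
  groups <- as.factor(groups)
  check_groups(values, groups, min_groups = 2, min_per_group = 1)
  h <- kw_statistic(values, groups)
  g <- nlevels(groups)
  if (exact) {
    p <- kw_exact_p(values, groups, h)
    method <- "kruskal-wallis (exact enumeration)"
  } else {
    p <- if (is.na(h)) 1 else pchisq(h, df = g - 1, lower.tail = FALSE)
    method <- "kruskal-wallis (chi-square)"
  }
  tibble(statistic = ifelse(is.na(h), 0, h), df = g - 1, p_value = p,
         method = method)
}

kw_statistic <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr == 0) return(NA_real_)  # all values tied
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  h / tie_corr
}

kw_exact_p <- function(values, groups, h_obs) {
  if (is.na(h_obs)) return(1)
  n <- length(values)
  if (n > 10) abort("Exact Kruskal-Wallis enumeration supported for n <= 10 only.")
  null_h <- kw_exact_null(values, as.vector(table(groups)))
  mean(null_h >= h_obs - 1e-12, na.rm = TRUE)
}

# Exact null distribution of H: the statistic under every distinct
# assignment of the observed values to groups of the given sizes
# (exchangeable under the null; group labels enter only through sizes).
kw_exact_null <- function(values, sizes) {
  assignments <- group_assignments(length(values), sizes)
  apply(assignments, 2, function(g) kw_statistic(values, factor(g)))
}

# All distinct partitions of positions 1..n into groups of the given sizes,
# as columns of group labels.
group_assignments <- function(n, sizes) {
  recurse <- function(pool, sizes_left, label) {
    if (length(sizes_left) == 1) {
      out <- matrix(label, length(pool), 1)
      rownames(out) <- as.character(pool)
      return(out)
    }
    k <- sizes_left[1]
    picks <- combn(pool, k)
    cols <- lapply(seq_len(ncol(picks)), function(j) {
      chosen <- picks[, j]
      rest <- recurse(setdiff(pool, chosen), sizes_left[-1], label + 1L)
      block <- matrix(0L, length(pool), ncol(rest))
      rownames(block) <- as.character(pool)
      block[as.character(chosen), ] <- label
      block[rownames(rest), ] <- rest
      block
    })
    do.call(cbind, cols)
  }
  out <- recurse(seq_len(n), sizes, 1L)
  out[order(as.integer(rownames(out))), , drop = FALSE]
}

check_groups <- function(values, groups, min_groups, min_per_group) {
  if (length(values) != length(groups)) abort("values and groups differ in length.")
  tab <- table(groups)
  if (length(tab) < min_groups) {
    abort(sprintf("Need >= %d groups, got %d.", min_groups, length(tab)))
  }
  if (any(tab < min_per_group)) {
    abort(sprintf("Every group needs >= %d observations.", min_per_group))
  }
  invisible(TRUE)
}

#' Pooled-variance two-sample t-test
#'
#' Two-sided, equal-variance two-sample t with `n1 + n2 - 2` degrees of
#' freedom. Degenerate inputs: zero pooled variance with equal means gives
#' `t = 0, p = 1`; zero pooled variance with unequal means gives `p = 0`
#' with `degenerate = TRUE`.
#'
#' @param values Numeric vector.
#' @param groups Two-level label per value, each level with >= 2 values.
#' @return Tibble: `statistic` (t), `df`, `p_value`, `degenerate`.
#' @export
two_group_t_test <- function(values, groups) {
  groups <- as.factor(groups)
  check_groups(values, groups, min_groups = 2, min_per_group = 2)
  if (nlevels(groups) != 2) abort("Exactly two groups required.")
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  delta <- mean(y) - mean(x)
  if (sp2 == 0) {
    if (delta == 0) return(tibble(statistic = 0, df = df, p_value = 1, degenerate = FALSE))
    return(tibble(statistic = sign(delta) * Inf, df = df, p_value = 0, degenerate = TRUE))
  }
  t <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble(statistic = t, df = df, p_value = 2 * pt(abs(t), df, lower.tail = FALSE),
         degenerate = FALSE)
}

#' One-way ANOVA with Bonferroni-corrected significance call
#'
#' Classical between/within F with `(g - 1, N - g)` degrees of freedom; the
#' gene is called significant iff `p < alpha / n_tests` (standard Bonferroni
#' over the number of genes screened in the same run).
#'
#' @param values Numeric vector.
#' @param groups Labels (>= 2 groups, each >= 2 values).
#' @param alpha Family-wise significance level.
#' @param n_tests Number of tests in the family (Bonferroni divisor).
#' @return Tibble: `statistic` (F), `df1`, `df2`, `p_value`, `significant`.
#' @export
one_way_anova_bonferroni <- function(values, groups, alpha = 0.01, n_tests = 1) {
  groups <- as.factor(groups)
  check_groups(values, groups, min_groups = 2, min_per_group = 2)
  g <- nlevels(groups)
  n <- length(values)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df1 <- g - 1; df2 <- n - g
  if (ss_within == 0) {
    if (ss_between == 0) {
      return(tibble(statistic = 0, df1 = df1, df2 = df2, p_value = 1, significant = FALSE))
    }
    return(tibble(statistic = Inf, df1 = df1, df2 = df2, p_value = 0, significant = TRUE))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  tibble(statistic = f, df1 = df1, df2 = df2, p_value = p,
         significant = p < alpha / n_tests)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values (monotone non-decreasing in p-rank,
#'   capped at 1), in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p_values[o]))[ro]
  q
}

#' Hypergeometric over-representation test
#'
#' For each annotation category, the upper-tail hypergeometric probability of
#' drawing at least the observed number of category members when sampling
#' `|study|` genes without replacement from the universe. Categories with
#' `p < threshold` are flagged over-represented.
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `universe`).
#' @param universe Character vector of universe gene ids.
#' @param annotation Data frame with columns `gene_id`, `category`
#'   (a gene may carry several categories); genes outside the universe are
#'   ignored.
#' @param threshold Significance threshold for the over-representation flag.
#' @return Tibble per category: `category`, `n_category`, `n_study`,
#'   `overlap`, `p_value`, `enriched`.
#' @export
hypergeometric_enrichment <- function(study, universe, annotation, threshold = 0.1) {
  study <- unique(study); universe <- unique(universe)
  extra <- setdiff(study, universe)
  if (length(extra) > 0) {
    abort(sprintf("Study set not contained in universe (e.g. %s).", extra[1]))
  }
  stopifnot(all(c("gene_id", "category") %in% names(annotation)))
  ann <- annotation |>
    filter(.data$gene_id %in% .env$universe) |>
    distinct(.data$gene_id, .data$category)
  n_total <- length(universe)
  n_study <- length(study)
  ann |>
    group_by(.data$category) |>
    summarise(
      n_category = dplyr::n(),
      overlap = sum(.data$gene_id %in% .env$study),
      .groups = "drop"
    ) |>
    mutate(
      n_study = n_study,
      p_value = purrr::map2_dbl(.data$overlap, .data$n_category,
                                ~ hyper_upper_tail(.x, .y, n_total, n_study)),
      enriched = .data$p_value < threshold
    ) |>
    select("category", "n_category", "n_study", "overlap", "p_value", "enriched")
}

# P(X >= k) for X ~ Hypergeometric(categ K, universe N, draws n), by direct
# summation on the log scale.
hyper_upper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  i <- seq(k, min(K, n))
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}
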