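#' Sarle's bimodality coefficient
#'
#' `b = (g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))` with `g1` the
#' bias-corrected sample skewness and `g2` the bias-corrected sample excess
#' kurtosis. For a uniform distribution `b` tends to 5/9 (~0.5556), which is
#' the conventional benchmark: distributions with `b > 0.555` are flagged
#' bimodal; a normal distribution gives `b` near 1/3.
#'
#' @param values Numeric vector, at least 4 finite values with nonzero
#'   variance; otherwise `NA` is returned with a warning and the value is
#'   treated as not bimodal.
#' @return Numeric `b` in (0, 1], with attribute `bimodal` (logical).
#' @export
bimodality_coefficient <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4 || sd(values) == 0) {
    warn("Bimodality coefficient undefined (n < 4 or zero variance); treated as not bimodal.")
    return(structure(NA_real_, bimodal = FALSE))
  }
  m <- mean(values)
  s <- sd(values)
  # bias-corrected sample skewness G1 and excess kurtosis G2
  g1 <- sum((values - m)^3) / n / (sum((values - m)^2) / n)^1.5
  g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g2 <- sum((values - m)^4) / n / (sum((values - m)^2) / n)^2 - 3
  g2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  b <- (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  structure(b, bimodal = b > bimodality_threshold())
}

#' Benchmark threshold for calling a distribution bimodal
#' @return 0.555, just below the uniform-distribution value 5/9.
#' @export
bimodality_threshold <- function() 0.555

# Farthest-point ("k-means++"-style) seeding: first center drawn at random,
# each further center is the point maximizing its minimal distance to the
# centers chosen so far. Deterministic given the first pick.
farthest_point_centers <- function(x, k) {
  idx <- integer(k)
  idx[1] <- sample.int(nrow(x), 1)
  d2min <- colSums((t(x) - x[idx[1], ])^2)
  if (k > 1) {
    for (j in 2:k) {
      idx[j] <- which.max(d2min)
      d2min <- pmin(d2min, colSums((t(x) - x[idx[j], ])^2))
    }
  }
  x[idx, , drop = FALSE]
}

# Seeded k-means: farthest-point seeding, `restarts` restarts, best
# within-cluster sum of squares wins. Returns a stats::kmeans fit.
seeded_kmeans <- function(x, k, seed, restarts = 10) {
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- farthest_point_centers(x, k)
    centers <- centers + 1e-9 * matrix(rnorm(length(centers)), nrow(centers))
    fit <- suppressWarnings(
      kmeans(x, centers = centers, iter.max = 50, algorithm = "Lloyd")
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

gmm_bimodal <- function(values, max_points = 5000, seed = 1) {
  if (!requireNamespace("mclust", quietly = TRUE)) {
    abort("criterion = 'gmm_bic' requires the mclust package.")
  }
  if (length(values) > max_points) {
    set.seed(seed)
    values <- sample(values, max_points)
  }
  fit <- mclust::Mclust(values, G = 1:2, modelNames = "V", verbose = FALSE)
  fit$G == 2
}

#' Select the unimodal gene set by a k-means intensity sweep
#'
#' Pooled log2 intensities of whole-array data are typically bimodal: a
#' low-intensity mode of background-level probes sits under the expressed
#' genes. The sweep clusters genes by their intensity profiles (Euclidean on
#' per-gene sample vectors) for increasing k until exactly one cluster is
#' bimodal (pooled member intensities, Sarle's coefficient by default) *and*
#' that cluster has the lowest mean intensity. All genes outside that cluster
#' form the unimodal set. If no k up to `k_max` satisfies the rule, the
#' partition at `k_max` is returned with `converged = FALSE` and the unimodal
#' set is all genes outside any bimodal low cluster found (all genes when
#' none is bimodal).
#'
#' @param expr An `expr_tbl` (replicate-level or averaged).
#' @param k_max Largest k to try (sweep runs k = 2..k_max).
#' @param seed Seed for the k-means restarts.
#' @param criterion `"sarle"` (default) or `"gmm_bic"` (two-component
#'   Gaussian mixture preferred by BIC; requires mclust).
#' @param restarts Seeded k-means restarts per k.
#' @return A `bimodality_partition`: list with `k`, `assignment` (tibble
#'   `gene_id`, `cluster`), `clusters` (per-cluster `n_genes`, `mean_intensity`,
#'   `b`, `bimodal`), `unimodal_set` (character vector), `bimodal_cluster`,
#'   `converged`, `criterion`, `seed`.
#' @export
unimodal_filter <- function(expr, k_max = 15, seed = 1,
                            criterion = c("sarle", "gmm_bic"), restarts = 10) {
  criterion <- match.arg(criterion)
  if (k_max < 2) abort("k_max must be >= 2.")
  x <- expr_matrix(expr)
  if (nrow(x) < k_max) abort("Fewer genes than k_max clusters.")
  result_at <- function(k) {
    fit <- seeded_kmeans(x, k, seed = seed + k, restarts = restarts)
    cl <- fit$cluster
    stats <- purrr::map_dfr(seq_len(k), function(j) {
      pooled <- as.vector(x[cl == j, , drop = FALSE])
      b <- suppressWarnings(bimodality_coefficient(pooled))
      bimodal <- if (criterion == "sarle") {
        isTRUE(attr(b, "bimodal"))
      } else {
        length(pooled) >= 8 && gmm_bimodal(pooled, seed = seed)
      }
      tibble(cluster = j, n_genes = sum(cl == j),
             mean_intensity = mean(pooled), b = as.numeric(b),
             bimodal = bimodal)
    })
    list(cl = cl, stats = stats)
  }
  final <- NULL
  for (k in 2:k_max) {
    res <- result_at(k)
    bim <- which(res$stats$bimodal)
    if (length(bim) == 1) {
      min_mean <- min(res$stats$mean_intensity)
      # ties in "minimal mean" break toward the larger cluster
      minimal <- res$stats |>
        filter(.data$mean_intensity <= min_mean + 1e-12) |>
        arrange(dplyr::desc(.data$n_genes))
      if (res$stats$cluster[bim] == minimal$cluster[1]) {
        final <- c(res, list(k = k, converged = TRUE))
        break
      }
    }
  }
  if (is.null(final)) {
    final <- c(result_at(k_max), list(k = k_max, converged = FALSE))
  }
  bim_cluster <- if (final$converged) which(final$stats$bimodal) else {
    low_bim <- final$stats |> filter(.data$bimodal) |>
      arrange(.data$mean_intensity)
    if (nrow(low_bim) > 0) low_bim$cluster[1] else NA_integer_
  }
  unimodal <- if (is.na(bim_cluster[1])) expr$gene_id else
    expr$gene_id[final$cl != bim_cluster]
  structure(list(
    k = final$k,
    assignment = tibble(gene_id = expr$gene_id, cluster = final$cl),
    clusters = final$stats,
    unimodal_set = unimodal,
    bimodal_cluster = bim_cluster,
    converged = final$converged,
    criterion = criterion,
    seed = seed
  ), class = "bimodality_partition")
}

#' @export
print.bimodality_partition <- function(x, ...) {
  cat(sprintf("k-means intensity sweep: k = %d (%s), %d/%d genes unimodal\n",
              x$k, if (x$converged) "converged" else "no single bimodal low cluster",
              length(x$unimodal_set), nrow(x$assignment)))
  print(x$clusters)
  invisible(x)
}

#' @rdname unimodal_filter
#' @param x A `bimodality_partition`.
#' @param ... Unused.
#' @export
tidy.bimodality_partition <- function(x, ...) x$clusters

#' @rdname unimodal_filter
#' @export
glance.bimodality_partition <- function(x, ...) {
  tibble(k = x$k, converged = x$converged,
         n_genes = nrow(x$assignment),
         n_unimodal = length(x$unimodal_set),
         bimodal_cluster = x$bimodal_cluster[1],
         criterion = x$criterion)
}
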