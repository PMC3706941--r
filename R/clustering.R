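#' Pearson correlation distance matrix
#'
#' `d_ij = 1 - r_ij` with `r` the Pearson correlation between sample columns
#' (`axis = "samples"`) or gene rows (`axis = "genes"`). Distances lie in
#' `[0, 2]`, the diagonal is zero, and the matrix is symmetric. The distance
#' is invariant to per-vector affine rescaling (`r` is shift/scale
#' invariant).
#'
#' @param expr An `expr_tbl` or numeric matrix (genes x samples).
#' @param axis `"samples"` (default) or `"genes"`.
#' @return Symmetric numeric matrix of `1 - r` distances.
#' @export
pearson_distance_matrix <- function(expr, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  x <- if (is.matrix(expr)) expr else expr_matrix(expr)
  if (axis == "genes") x <- t(x)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[which(sds == 0)[1]] %||% which(sds == 0)[1]
    abort(sprintf("Zero-variance vector '%s': Pearson distance undefined.", bad))
  }
  if (ncol(x) < 2) abort("Need >= 2 vectors.")
  d <- 1 - cor(x)
  diag(d) <- 0
  d
}

#' Agglomerative dendrogram from a distance matrix
#'
#' Average (default), complete or Ward linkage ("ward" maps to `hclust`'s
#' `ward.D2`, the Ward criterion on distances). The merge tree is
#' deterministic; with equal merge distances the pair with the lowest
#' indices merges first (hclust's convention).
#'
#' @param d A symmetric distance matrix (e.g. from
#'   [pearson_distance_matrix()]) or a `dist` object.
#' @param linkage `"average"`, `"complete"` or `"ward"`.
#' @return An `hclust` object.
#' @export
hierarchical_dendrogram <- function(d, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  method <- if (linkage == "ward") "ward.D2" else linkage
  if (!inherits(d, "dist")) d <- as.dist(d)
  hclust(d, method = method)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are height differences along each root path, so leaf
#' depths equal the merge heights.
#'
#' @param hc An `hclust` object.
#' @param path Optional file path; when given, the tree is written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Cut a sample dendrogram at the highest merge into two groups
#'
#' @param hc An `hclust` object over samples.
#' @return Tibble `sample`, `group` (1 or 2).
#' @export
cut_two_groups <- function(hc) {
  cl <- stats::cutree(hc, k = 2)
  tibble(sample = names(cl), group = as.integer(cl))
}

#' k-means clustering of gene expression profiles
#'
#' Pearson-metric profile k-means: each gene profile is standardized to zero
#' mean and unit variance, making squared Euclidean distance proportional to
#' `1 - r`; Lloyd iterations then run on the standardized profiles with
#' seeded farthest-point initialization and multiple restarts (best
#' within-cluster sum of squares kept). Centroids are means of the member
#' standardized profiles. Each cluster gets a monotonicity label from its
#' centroid's stage means: `up` if they strictly increase over stages,
#' `down` if strictly decrease, else `other`.
#'
#' Genes with constant profiles (zero variance) cannot be standardized; they
#' are assigned to the nearest centroid by Euclidean distance on the raw
#' profile with a warning.
#'
#' @param expr An `expr_tbl`.
#' @param k Number of clusters (>= 2; fewer genes than k is an error).
#' @param metric `"pearson"` (standardized profiles) or `"euclidean"` (raw).
#' @param seed Seed for the restarts.
#' @param restarts Number of seeded restarts.
#' @return A `profile_clusters`: list with `k`, `metric`, `assignment`
#'   (tibble `gene_id`, `cluster`), `centroids` (k x samples matrix),
#'   `cluster_info` (tibble `cluster`, `n_genes`, `monotonicity`),
#'   `tot_withinss`, `seed`.
#' @export
kmeans_profiles <- function(expr, k, metric = c("pearson", "euclidean"),
                            seed = 1, restarts = 10) {
  metric <- match.arg(metric)
  if (k < 2) abort("k must be >= 2.")
  x <- expr_matrix(expr)
  if (nrow(x) < k) abort("Fewer genes than clusters.")
  sds <- apply(x, 1, sd)
  const <- sds == 0
  if (metric == "pearson") {
    z <- x
    z[!const, ] <- t(scale(t(x[!const, , drop = FALSE])))
    z[const, ] <- 0
    if (any(const)) {
      warn(sprintf("%d constant-profile gene(s) assigned by Euclidean fallback.",
                   sum(const)))
    }
  } else {
    z <- x
  }
  work <- z[!const | metric == "euclidean", , drop = FALSE]
  fit <- seeded_kmeans(work, k, seed = seed, restarts = restarts)
  cl <- integer(nrow(x))
  cl[!const | metric == "euclidean"] <- fit$cluster
  if (metric == "pearson" && any(const)) {
    for (i in which(const)) {
      d2 <- rowSums(sweep(fit$centers, 2, x[i, ])^2)
      cl[i] <- which.min(d2)
    }
  }
  info <- expr_samples(expr)
  mono <- vapply(seq_len(k), function(j) {
    sm <- tapply(fit$centers[j, ], info$stage, mean)
    sm <- sm[order(as.integer(names(sm)))]
    if (all(diff(sm) > 0)) "up" else if (all(diff(sm) < 0)) "down" else "other"
  }, character(1))
  structure(list(
    k = k, metric = metric,
    assignment = tibble(gene_id = expr$gene_id, cluster = cl),
    centroids = fit$centers,
    cluster_info = tibble(cluster = seq_len(k),
                          n_genes = as.integer(tabulate(cl, k)),
                          monotonicity = mono),
    tot_withinss = fit$tot.withinss,
    seed = seed
  ), class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat(sprintf("Profile k-means: k = %d (%s metric), %d genes, tot within-SS %.3f\n",
              x$k, x$metric, nrow(x$assignment), x$tot_withinss))
  print(x$cluster_info)
  invisible(x)
}

#' @rdname kmeans_profiles
#' @param x A `profile_clusters`.
#' @param ... Unused.
#' @export
tidy.profile_clusters <- function(x, ...) {
  left_join(x$assignment, x$cluster_info, by = "cluster")
}

#' @rdname kmeans_profiles
#' @export
glance.profile_clusters <- function(x, ...) {
  tibble(k = x$k, metric = x$metric, n_genes = nrow(x$assignment),
         tot_withinss = x$tot_withinss,
         n_up = sum(x$cluster_info$monotonicity == "up"),
         n_down = sum(x$cluster_info$monotonicity == "down"))
}
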