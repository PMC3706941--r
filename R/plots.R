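#' @rdname unimodal_filter
#' @param object A `bimodality_partition` (with the `expr` it was fitted on
#'   for the pooled histogram).
#' @param expr The expression table the partition was computed from.
#' @export
autoplot.bimodality_partition <- function(object, expr, ...) {
  df <- as_tibble(expr) |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample", values_to = "log2_intensity") |>
    left_join(object$assignment, by = "gene_id") |>
    mutate(status = ifelse(.data$cluster %in% object$bimodal_cluster,
                           "bimodal low cluster", "unimodal"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_intensity, fill = .data$status)) +
    ggplot2::geom_histogram(bins = 80, position = "stack") +
    ggplot2::labs(x = "log2 intensity (pooled)", y = "values",
                  fill = NULL,
                  title = sprintf("Intensity k-means sweep (k = %d)", object$k)) +
    ggplot2::theme_minimal()
}

#' @rdname sam
#' @param object A `sam_result`.
#' @export
autoplot.sam_result <- function(object, ...) {
  df <- object$genes |> arrange(.data$d) |>
    mutate(expected = sort(.data$dbar))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$d,
                                   colour = .data$called)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "expected d (permutation order statistics)",
                  y = "observed d",
                  colour = "called",
                  title = sprintf("SAM %s: delta = %.3g, FDR = %.3g",
                                  object$mode, object$delta, object$fdr)) +
    ggplot2::theme_minimal()
}

#' @rdname pca_uv
#' @param object A `latent_model`.
#' @export
autoplot.latent_model <- function(object, ...) {
  sc <- object$scores
  axes <- setdiff(names(sc), c("sample", "class"))[1:2]
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data[[axes[1]]], y = .data[[axes[2]]]))
  p <- if ("class" %in% names(sc)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$class))
  } else {
    p + ggplot2::geom_point()
  }
  title <- if (object$kind == "pca") {
    sprintf("UV PCA (cumulative R2X = %.3f)", object$r2x_cum)
  } else {
    sprintf("OPLS-DA %s: R2X = %.3f, Q2 = %.3f",
            object$notation, object$r2x_cum, object$q2)
  }
  p + ggplot2::labs(title = title) + ggplot2::theme_minimal()
}

#' @rdname kmeans_profiles
#' @param object A `profile_clusters`.
#' @export
autoplot.profile_clusters <- function(object, ...) {
  cen <- as_tibble(object$centroids, .name_repair = "minimal")
  names(cen) <- colnames(object$centroids)
  cen$cluster <- seq_len(object$k)
  df <- cen |>
    tidyr::pivot_longer(-"cluster", names_to = "sample", values_to = "value") |>
    mutate(stage = parse_sample_names(unique(.data$sample))$stage[match(.data$sample, unique(.data$sample))]) |>
    group_by(.data$cluster, .data$stage) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    left_join(object$cluster_info, by = "cluster")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$value,
                                   group = .data$cluster,
                                   colour = .data$monotonicity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "developmental stage", y = "centroid (standardized log2)",
                  title = sprintf("Profile k-means (k = %d, %s)", object$k, object$metric)) +
    ggplot2::theme_minimal()
}

#' @rdname permutation_validation
#' @param object A `permutation_validation`.
#' @export
autoplot.permutation_validation <- function(object, ...) {
  df <- tidyr::pivot_longer(object$perms, c("r2y", "q2"),
                            names_to = "metric", values_to = "value")
  obs <- tibble(metric = c("r2y", "q2"),
                value = c(object$observed_r2y, object$observed_q2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = .data$value),
                        colour = "red", linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(title = sprintf("Permutation validation (%d permutations): p(Q2) = %.3g",
                                  object$n_perms, object$p_q2),
                  x = "permuted value", y = "count") +
    ggplot2::theme_minimal()
}
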