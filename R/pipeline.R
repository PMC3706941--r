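#' Per-gene Kruskal-Wallis screen over a grouping of samples
#'
#' Applies the tie-corrected Kruskal-Wallis test to every gene row with the
#' given sample grouping and BH q-values.
#'
#' @param expr An `expr_tbl`.
#' @param groups Group label per sample column, or a descriptor field name
#'   (`"vineyard"`, `"stage"`, `"year"`).
#' @param alpha Significance level for the `significant` flag.
#' @param exact If `TRUE` (only for <= 10 samples), p-values come from the
#'   exact permutation null of H computed once from the untied rank
#'   configuration; essential at very small group sizes, where the
#'   chi-square approximation cannot reach small p-values at all.
#' @return Tibble: `gene_id`, `statistic`, `p_value`, `q_value`, `significant`.
#' @export
kw_screen <- function(expr, groups, alpha = 0.01, exact = FALSE) {
  labels <- as.factor(resolve_labels(expr, groups))
  check_groups(rep(0, ncol(expr) - 1), labels, min_groups = 2, min_per_group = 1)
  x <- expr_matrix(expr)
  g <- nlevels(labels)
  if (exact) {
    n <- ncol(x)
    if (n > 10) abort("exact = TRUE supported for <= 10 samples only.")
    null_h <- sort(kw_exact_null(seq_len(n), as.vector(table(labels))))
    res <- apply(x, 1, function(v) {
      h <- kw_statistic(v, labels)
      if (is.na(h)) return(c(0, 1))
      p <- 1 - findInterval(h - 1e-12, null_h) / length(null_h)
      c(h, p)
    })
  } else {
    res <- apply(x, 1, function(v) {
      h <- kw_statistic(v, labels)
      if (is.na(h)) c(0, 1) else c(h, pchisq(h, df = g - 1, lower.tail = FALSE))
    })
  }
  out <- tibble(gene_id = expr$gene_id, statistic = res[1, ], p_value = res[2, ])
  out$q_value <- benjamini_hochberg(out$p_value)
  out$significant <- out$p_value < alpha
  out
}

#' Call environmentally plastic genes
#'
#' A gene is plastic when its expression differs among vineyards: the
#' Kruskal-Wallis test across vineyard groups (all stages and replicates
#' pooled per vineyard) at `p < alpha`, applied to the unimodal gene set of
#' a one-year, multi-vineyard table. The summary also reports, per vineyard,
#' the number of genes modulated during ripening (Kruskal-Wallis across the
#' stages within that vineyard at the same `alpha`), their average over
#' vineyards, and the plastic set as a percentage of that average and of the
#' whole array.
#'
#' @param expr An `expr_tbl` (one year, >= 2 vineyards; replicate-level by
#'   default).
#' @param unimodal Character vector of unimodal gene ids (e.g. from
#'   [unimodal_filter()]); defaults to all genes.
#' @param alpha Significance level (study convention 0.01).
#' @param n_array_genes Total genes on the array, for the array-content
#'   percentage; defaults to the number of genes in `expr`.
#' @return A `plastic_call`: list with `plastic` (gene ids), `tests`
#'   (per-gene KW tibble), `per_vineyard` (tibble `vineyard`, `n_modulated`),
#'   `summary` (one-row tibble: `n_plastic`, `avg_modulated`,
#'   `pct_of_modulated`, `pct_of_array`).
#' @export
call_plastic_genes <- function(expr, unimodal = NULL, alpha = 0.01,
                               n_array_genes = NULL) {
  info <- expr_samples(expr)
  if (length(unique(info$vineyard)) < 2) abort("Need >= 2 vineyards.")
  n_array_genes <- n_array_genes %||% nrow(expr)
  sub <- if (is.null(unimodal)) expr else expr_subset(expr, genes = intersect(expr$gene_id, unimodal))
  tests <- kw_screen(sub, "vineyard", alpha = alpha)
  plastic <- tests$gene_id[tests$significant]
  per_vineyard <- purrr::map_dfr(unique(info$vineyard), function(v) {
    cols <- info$sample[info$vineyard == v]
    sub_v <- expr_subset(sub, samples = cols)
    # per-vineyard stage screens have tiny n; use the exact null when feasible
    res <- kw_screen(sub_v, "stage", alpha = alpha, exact = length(cols) <= 10)
    tibble(vineyard = v, n_modulated = sum(res$significant))
  })
  avg_mod <- mean(per_vineyard$n_modulated)
  summary <- tibble(
    n_plastic = length(plastic),
    avg_modulated = avg_mod,
    pct_of_modulated = plasticity_rates(length(plastic), avg_mod, n_array_genes)$pct_of_modulated,
    pct_of_array = plasticity_rates(length(plastic), avg_mod, n_array_genes)$pct_of_array
  )
  structure(list(plastic = plastic, tests = tests, per_vineyard = per_vineyard,
                 summary = summary, alpha = alpha),
            class = "plastic_call")
}

#' @export
print.plastic_call <- function(x, ...) {
  cat(sprintf("Plastic-gene call (KW across vineyards, alpha = %g): %d plastic genes\n",
              x$alpha, length(x$plastic)))
  print(x$summary)
  invisible(x)
}

#' Headline plasticity percentages
#'
#' Expresses a plastic-gene count as a percentage of (a) the average number
#' of ripening-modulated genes per vineyard and (b) the array gene content.
#'
#' @param n_plastic Number of plastic genes.
#' @param avg_modulated Average per-vineyard count of ripening-modulated genes.
#' @param n_array_genes Total genes on the array.
#' @return One-row tibble: `pct_of_modulated`, `pct_of_array` (percent units).
#' @export
plasticity_rates <- function(n_plastic, avg_modulated, n_array_genes) {
  tibble(pct_of_modulated = 100 * n_plastic / avg_modulated,
         pct_of_array = 100 * n_plastic / n_array_genes)
}

#' Associate genes with an environmental or agronomic factor
#'
#' Kruskal-Wallis screen of the unimodal set across the levels of a
#' vineyard-level factor (e.g. trellis system, macro-area, rootstock), with
#' BH q-values and a permutation FDR estimate: factor levels are permuted
#' across vineyards (whole vineyards keep their samples together) and the
#' FDR is the median permuted significant count over the observed one.
#'
#' @param expr An `expr_tbl`.
#' @param factor_map Data frame `vineyard`, `level` assigning each vineyard
#'   one factor level (>= 2 levels, each with >= 1 vineyard).
#' @param unimodal Optional unimodal gene ids.
#' @param alpha Significance level.
#' @param n_perms Label permutations for the FDR estimate.
#' @param seed Seed.
#' @return A `factor_association`: list with `significant` (gene ids),
#'   `tests`, `fdr` (permutation estimate), `fdr_bh` (smallest q among
#'   called genes' upper bound = max q of called set), `n_perms`, `seed`.
#' @export
factor_association <- function(expr, factor_map, unimodal = NULL,
                               alpha = 0.01, n_perms = 100, seed = 1) {
  stopifnot(all(c("vineyard", "level") %in% names(factor_map)))
  info <- expr_samples(expr)
  missing <- setdiff(unique(info$vineyard), factor_map$vineyard)
  if (length(missing) > 0) {
    abort(sprintf("No factor level for vineyard(s): %s", paste(missing, collapse = ", ")))
  }
  lv <- setNames(as.character(factor_map$level), factor_map$vineyard)
  labels <- lv[info$vineyard]
  if (length(unique(labels)) < 2) abort("Factor needs >= 2 levels with samples.")
  sub <- if (is.null(unimodal)) expr else expr_subset(expr, genes = intersect(expr$gene_id, unimodal))
  tests <- kw_screen(sub, labels, alpha = alpha)
  n_sig <- sum(tests$significant)
  set.seed(seed)
  vineyards <- unique(factor_map$vineyard)
  perm_counts <- vapply(seq_len(n_perms), function(i) {
    lv_p <- setNames(sample(lv[vineyards]), vineyards)
    res_p <- kw_screen(sub, lv_p[info$vineyard], alpha = alpha)
    sum(res_p$significant)
  }, numeric(1))
  fdr <- if (n_sig == 0) 0 else min(1, median(perm_counts) / n_sig)
  structure(list(
    significant = tests$gene_id[tests$significant], tests = tests,
    fdr = fdr, perm_counts = perm_counts,
    fdr_bh = if (n_sig == 0) NA_real_ else max(tests$q_value[tests$significant]),
    alpha = alpha, n_perms = n_perms, seed = seed
  ), class = "factor_association")
}

#' @export
print.factor_association <- function(x, ...) {
  cat(sprintf("Factor association (KW, alpha = %g): %d genes; permutation FDR = %.4g (%d perms); max BH q among called = %.4g\n",
              x$alpha, length(x$significant), x$fdr, x$n_perms, x$fdr_bh))
  invisible(x)
}

#' Harvest-stage analysis: modulated genes and the two-group vineyard split
#'
#' On a single-stage, multi-vineyard replicate-level table: (1) SAM
#' multiclass across vineyards at `fdr_target`; (2) retain genes whose
#' largest absolute log2 difference of vineyard means over all vineyard
#' pairs is at least `log2(fold_threshold)`; (3) build the sample dendrogram
#' (1 - Pearson r on replicate-averaged samples, configurable linkage) and
#' cut it into two vineyard groups at the highest merge; (4) confirm the
#' split by a per-gene pooled-variance t-test between the two groups at
#' `alpha_t`.
#'
#' @param expr Single-stage replicate-level `expr_tbl` (>= 3 vineyards).
#' @param fdr_target SAM FDR target (study convention 0.001).
#' @param fold_threshold Linear fold-change screen (study convention 2).
#' @param alpha_t t-test significance level (study convention 0.05).
#' @param linkage Dendrogram linkage.
#' @param n_perms,seed SAM permutation settings.
#' @return A `harvest_analysis`: list with `modulated` (SAM-significant gene
#'   ids), `retained` (after the fold screen), `fold_changes` (tibble
#'   `gene_id`, `max_abs_log2fc`), `dendrogram` (hclust), `groups` (tibble
#'   `vineyard`, `group`), `t_tests` (per-gene tibble), `confirmed`
#'   (gene ids significant between groups), `sam` (the `sam_result`).
#' @export
harvest_analysis <- function(expr, fdr_target = 0.001, fold_threshold = 2,
                             alpha_t = 0.05, linkage = "average",
                             n_perms = 100, seed = 1) {
  info <- expr_samples(expr)
  if (length(unique(info$stage)) != 1) abort("Expected a single-stage table.")
  if (length(unique(info$vineyard)) < 3) abort("Need >= 3 vineyards for the two-group partition.")
  sam_fit <- sam(expr, "vineyard", mode = "multiclass", fdr_target = fdr_target,
                 n_perms = n_perms, seed = seed)
  modulated <- sam_fit$significant
  fc <- max_pairwise_log2fc(expr, "vineyard")
  retained <- fc |>
    filter(.data$gene_id %in% modulated,
           .data$max_abs_log2fc >= log2(fold_threshold)) |>
    pull("gene_id")
  avg <- average_replicates(expr)
  hc <- hierarchical_dendrogram(pearson_distance_matrix(avg, "samples"),
                                linkage = linkage)
  cut <- cut_two_groups(hc)
  cut$vineyard <- parse_sample_names(cut$sample)$vineyard
  group_of <- setNames(cut$group, cut$vineyard)
  labels <- group_of[info$vineyard]
  sub <- expr_subset(expr, genes = retained)
  x <- expr_matrix(sub)
  t_tests <- purrr::map_dfr(seq_len(nrow(x)), function(i) {
    res <- two_group_t_test(x[i, ], labels)
    mutate(res, gene_id = sub$gene_id[i], .before = 1)
  })
  t_tests$significant <- t_tests$p_value < alpha_t
  structure(list(
    modulated = modulated, retained = retained, fold_changes = fc,
    dendrogram = hc, groups = distinct(cut[, c("vineyard", "group")]),
    t_tests = t_tests, confirmed = t_tests$gene_id[t_tests$significant],
    sam = sam_fit, fold_threshold = fold_threshold, alpha_t = alpha_t
  ), class = "harvest_analysis")
}

#' @export
print.harvest_analysis <- function(x, ...) {
  cat(sprintf("Harvest analysis: %d SAM-modulated, %d pass >= %g-fold screen, %d confirmed between the two vineyard groups (alpha = %g)\n",
              length(x$modulated), length(x$retained), x$fold_threshold,
              length(x$confirmed), x$alpha_t))
  invisible(x)
}

#' Largest pairwise log2 fold change across group means
#'
#' @param expr An `expr_tbl`.
#' @param groups Sample grouping (label vector or descriptor field name).
#' @return Tibble `gene_id`, `max_abs_log2fc`.
#' @export
max_pairwise_log2fc <- function(expr, groups) {
  labels <- as.factor(resolve_labels(expr, groups))
  x <- expr_matrix(expr)
  means <- vapply(levels(labels), function(l) {
    rowMeans(x[, labels == l, drop = FALSE])
  }, numeric(nrow(x)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  tibble(gene_id = expr$gene_id,
         max_abs_log2fc = unname(apply(means, 1, max) - apply(means, 1, min)))
}

#' Select monotone developmental marker genes
#'
#' Stage-modulated genes are the intersection of SAM multiclass across the
#' three stages (vineyards treated as replication) at `fdr_target` and
#' one-way ANOVA across stages with Bonferroni correction over the SAM
#' set at `alpha`. Their replicate-averaged profiles are clustered by
#' Pearson-metric k-means (`k` clusters); clusters whose centroid stage
#' means strictly increase (up) or decrease (down) are kept, and within the
#' kept direction the genes whose absolute stage3 - stage1 log2 difference
#' reaches the `percentile`-th percentile of that quantity are retained.
#'
#' @param expr One-year `expr_tbl` with all three stages (replicate-level).
#' @param fdr_target SAM FDR target (study convention 0.001).
#' @param alpha ANOVA family-wise level (study convention 0.01).
#' @param k Number of profile clusters (study convention 8).
#' @param percentile Fold-change percentile for the final screen (study
#'   convention 95).
#' @param n_perms,seed SAM permutations / k-means seeding.
#' @return A `marker_selection`: list with `up`, `down` (gene ids),
#'   `stage_modulated` (gene ids entering clustering), `clusters`
#'   (the `profile_clusters`), `fold_changes` (tibble `gene_id`,
#'   `direction`, `delta31`), `cutoffs` (named numeric).
#' @export
select_developmental_markers <- function(expr, fdr_target = 0.001,
                                         alpha = 0.01, k = 8, percentile = 95,
                                         n_perms = 100, seed = 1) {
  info <- expr_samples(expr)
  if (length(unique(info$stage)) < 3) abort("Need all three stages.")
  sam_fit <- sam(expr, "stage", mode = "multiclass", fdr_target = fdr_target,
                 n_perms = n_perms, seed = seed)
  sam_set <- sam_fit$significant
  if (length(sam_set) == 0) {
    warn("No stage-modulated genes found by SAM; empty marker sets.")
    return(empty_marker_selection())
  }
  sub <- expr_subset(expr, genes = sam_set)
  x <- expr_matrix(sub)
  stage_labels <- as.factor(info$stage)
  anova_keep <- vapply(seq_len(nrow(x)), function(i) {
    one_way_anova_bonferroni(x[i, ], stage_labels, alpha = alpha,
                             n_tests = length(sam_set))$significant
  }, logical(1))
  pool <- sub$gene_id[anova_keep]
  if (length(pool) < k) {
    warn("Too few stage-modulated genes to cluster; empty marker sets.")
    return(empty_marker_selection())
  }
  avg <- average_replicates(expr_subset(expr, genes = pool))
  clusters <- kmeans_profiles(avg, k = k, metric = "pearson", seed = seed)
  keep_info <- clusters$cluster_info |> filter(.data$monotonicity %in% c("up", "down"))
  if (nrow(keep_info) == 0) {
    warn("No monotone cluster found; empty marker sets.")
    return(empty_marker_selection(clusters = clusters))
  }
  avg_info <- expr_samples(avg)
  m_avg <- expr_matrix(avg)
  s1 <- rowMeans(m_avg[, avg_info$stage == 1, drop = FALSE])
  s3 <- rowMeans(m_avg[, avg_info$stage == max(avg_info$stage), drop = FALSE])
  delta <- s3 - s1
  assignment <- clusters$assignment |>
    left_join(clusters$cluster_info, by = "cluster") |>
    mutate(delta31 = delta[.data$gene_id])
  cutoffs <- c(up = NA_real_, down = NA_real_)
  pick <- function(direction) {
    genes <- assignment |> filter(.data$monotonicity == direction)
    if (nrow(genes) == 0) return(character(0))
    cut <- quantile(abs(genes$delta31), percentile / 100, names = FALSE)
    cutoffs[[direction]] <<- cut
    genes |> filter(abs(.data$delta31) >= cut) |> pull("gene_id")
  }
  up <- pick("up"); down <- pick("down")
  structure(list(
    up = up, down = down, stage_modulated = pool, clusters = clusters,
    fold_changes = assignment |>
      select("gene_id", direction = "monotonicity", "delta31"),
    cutoffs = cutoffs, sam = sam_fit, percentile = percentile
  ), class = "marker_selection")
}

empty_marker_selection <- function(clusters = NULL) {
  structure(list(up = character(0), down = character(0),
                 stage_modulated = character(0), clusters = clusters,
                 fold_changes = tibble(gene_id = character(0),
                                       direction = character(0),
                                       delta31 = numeric(0)),
                 cutoffs = c(up = NA_real_, down = NA_real_),
                 sam = NULL, percentile = NA_real_),
            class = "marker_selection")
}

#' @export
print.marker_selection <- function(x, ...) {
  cat(sprintf("Developmental markers: %d up, %d down (from %d stage-modulated genes)\n",
              length(x$up), length(x$down), length(x$stage_modulated)))
  invisible(x)
}

#' Select constitutive reference genes
#'
#' Per developmental stage, genes that are *not* significant under either
#' SAM multiclass across vineyards at `fdr_target` or one-way ANOVA across
#' vineyards at `alpha` are deemed constitutively expressed at that stage.
#' The three per-stage sets are intersected; the intersection is ranked by
#' standard deviation across the replicate-averaged samples of the full
#' design, and genes below the `100 - sd_percentile` percentile of that SD
#' (default: below the 1st percentile) form the constitutive reference set.
#'
#' @param expr One-year full-design `expr_tbl` (replicate-level).
#' @param fdr_target SAM FDR target.
#' @param alpha ANOVA significance level (no multiplicity correction; a
#'   liberal test keeps the constitutive call conservative).
#' @param sd_percentile Percentile defining "lowest SD" (study convention
#'   99: keep the bottom 1%).
#' @param n_perms,seed SAM permutation settings.
#' @return A `constitutive_selection`: list with `constitutive` (gene ids),
#'   `intersection` (per-stage-constitutive intersection), `per_stage`
#'   (named list of gene-id vectors), `sd_table` (tibble `gene_id`, `sd`,
#'   ranked ascending), `sd_cutoff`.
#' @export
select_constitutive_genes <- function(expr, fdr_target = 0.001, alpha = 0.01,
                                      sd_percentile = 99, n_perms = 100,
                                      seed = 1) {
  info <- expr_samples(expr)
  stages <- sort(unique(info$stage))
  per_stage <- lapply(stages, function(st) {
    cols <- info$sample[info$stage == st]
    sub <- expr_subset(expr, samples = cols)
    sam_fit <- sam(sub, "vineyard", mode = "multiclass", fdr_target = fdr_target,
                   n_perms = n_perms, seed = seed + st)
    x <- expr_matrix(sub)
    v_labels <- as.factor(expr_samples(sub)$vineyard)
    anova_sig <- vapply(seq_len(nrow(x)), function(i) {
      res <- one_way_anova_bonferroni(x[i, ], v_labels, alpha = alpha, n_tests = 1)
      res$p_value < alpha
    }, logical(1))
    setdiff(sub$gene_id[!anova_sig], sam_fit$significant)
  })
  names(per_stage) <- paste0("stage", stages)
  intersection <- Reduce(intersect, per_stage)
  if (length(intersection) == 0) {
    warn("Empty per-stage intersection; no constitutive genes.")
    return(structure(list(constitutive = character(0),
                          intersection = character(0), per_stage = per_stage,
                          sd_table = tibble(gene_id = character(0), sd = numeric(0)),
                          sd_cutoff = NA_real_),
                     class = "constitutive_selection"))
  }
  avg <- average_replicates(expr_subset(expr, genes = intersection))
  sds <- apply(expr_matrix(avg), 1, sd)
  sd_table <- tibble(gene_id = avg$gene_id, sd = sds) |> arrange(.data$sd)
  cutoff <- quantile(sds, (100 - sd_percentile) / 100, names = FALSE)
  constitutive <- sd_table$gene_id[sd_table$sd <= cutoff]
  structure(list(constitutive = constitutive, intersection = intersection,
                 per_stage = per_stage, sd_table = sd_table,
                 sd_cutoff = cutoff),
            class = "constitutive_selection")
}

#' @export
print.constitutive_selection <- function(x, ...) {
  cat(sprintf("Constitutive reference genes: %d (from a %d-gene three-stage intersection; SD cutoff %.4g)\n",
              length(x$constitutive), length(x$intersection), x$sd_cutoff))
  invisible(x)
}

#' Combine analysis outputs into one gene classification
#'
#' Labels every gene of the universe with mutually exclusive classes in the
#' priority order plastic > marker_up/marker_down > constitutive >
#' modulated_nonplastic > unclassified; conflicts (genes in several input
#' sets) are resolved by priority and recorded.
#'
#' @param universe Character vector of all gene ids in the run.
#' @param plastic,markers_up,markers_down,constitutive,modulated Gene-id
#'   vectors from the respective analyses (subsets of `universe`).
#' @return A `gene_classification`: list with `labels` (tibble `gene_id`,
#'   `label`), `conflicts` (tibble `gene_id`, `labels`).
#' @export
classify_genes <- function(universe, plastic = character(0),
                           markers_up = character(0),
                           markers_down = character(0),
                           constitutive = character(0),
                           modulated = character(0)) {
  sets <- list(plastic = plastic, marker_up = markers_up,
               marker_down = markers_down, constitutive = constitutive,
               modulated_nonplastic = modulated)
  stray <- setdiff(unique(unlist(sets)), universe)
  if (length(stray) > 0) {
    abort(sprintf("Gene(s) outside the universe: %s", paste(head(stray, 5), collapse = ", ")))
  }
  membership <- purrr::imap_dfr(sets, function(ids, lab) {
    if (length(ids) == 0) return(tibble(gene_id = character(0), label = character(0)))
    tibble(gene_id = unique(ids), label = lab)
  })
  priority <- c("plastic", "marker_up", "marker_down", "constitutive",
                "modulated_nonplastic")
  conflicts <- membership |>
    count(.data$gene_id) |> filter(.data$n > 1) |> pull("gene_id")
  conflict_tbl <- membership |>
    filter(.data$gene_id %in% conflicts) |>
    group_by(.data$gene_id) |>
    summarise(labels = paste(.data$label, collapse = "+"), .groups = "drop")
  winner <- membership |>
    mutate(rank = match(.data$label, priority)) |>
    arrange(.data$rank) |>
    distinct(.data$gene_id, .keep_all = TRUE) |>
    select("gene_id", "label")
  labels <- tibble(gene_id = universe) |>
    left_join(winner, by = "gene_id") |>
    mutate(label = dplyr::coalesce(.data$label, "unclassified"))
  structure(list(labels = labels, conflicts = conflict_tbl),
            class = "gene_classification")
}

#' @export
print.gene_classification <- function(x, ...) {
  cat("Gene classification:\n")
  print(count(x$labels, .data$label))
  if (nrow(x$conflicts) > 0) {
    cat(sprintf("%d gene(s) were in several sets (resolved by priority).\n",
                nrow(x$conflicts)))
  }
  invisible(x)
}

#' @rdname classify_genes
#' @param x A `gene_classification`.
#' @param ... Unused.
#' @export
tidy.gene_classification <- function(x, ...) x$labels

#' @rdname classify_genes
#' @export
glance.gene_classification <- function(x, ...) {
  x$labels |> count(.data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n")
}

#' Venn-style intersection of gene sets
#'
#' @param sets Named list of >= 2 character vectors of gene ids.
#' @return List with `counts` (tibble of every membership pattern and its
#'   count) and `intersection` (genes in all sets).
#' @export
intersect_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) abort("Need a list of >= 2 sets.")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  all_ids <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1) membership <- matrix(membership, nrow = 1,
                                                 dimnames = list(NULL, names(sets)))
  pattern <- apply(membership, 1, function(row) {
    paste(ifelse(row, "1", "0"), collapse = "")
  })
  counts <- tibble(pattern = pattern) |>
    count(.data$pattern, name = "n_genes") |>
    arrange(dplyr::desc(.data$pattern))
  list(counts = counts,
       intersection = if (length(all_ids) == 0) character(0) else
         all_ids[rowSums(membership) == length(sets)],
       sets = names(sets))
}
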