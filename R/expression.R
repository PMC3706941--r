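#' Build an expression table from a data frame
#'
#' An expression table is a tibble whose first column is `gene_id` and whose
#' remaining columns are samples named by the vineyard/year/stage/replicate
#' scheme (see [parse_sample_names()]), holding log2 fluorescence intensities.
#' The intensity scale is carried as an attribute (`"log2"`, `"log2ratio"`);
#' values supplied on a linear scale are log2-transformed on entry.
#'
#' @param df Data frame: first column gene identifiers, remaining columns
#'   numeric sample values.
#' @param scale One of `"log2"`, `"linear"`, `"log2ratio"`. With `"linear"`,
#'   all values must be positive and are stored as `log2(x)`.
#' @return A tibble of class `expr_tbl` with attribute `scale`.
#' @export
as_expr <- function(df, scale = c("log2", "linear", "log2ratio")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(df), ncol(df) >= 2)
  df <- as_tibble(df)
  names(df)[1] <- "gene_id"
  df$gene_id <- as.character(df$gene_id)
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate gene_id(s): %s", paste(head(dup, 5), collapse = ", ")))
  }
  sample_names <- names(df)[-1]
  if (anyDuplicated(sample_names)) {
    abort("Duplicate sample names in header.")
  }
  parse_sample_names(sample_names)  # validates; errors name the offending field
  for (j in seq(2, ncol(df))) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      abort(sprintf("Non-numeric value at row %d, column '%s'.",
                    if (is.na(bad)) 1L else bad, names(df)[j]))
    }
    if (anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1]
      abort(sprintf("Missing/non-finite value at row %d (gene '%s'), column '%s'.",
                    bad, df$gene_id[bad], names(df)[j]))
    }
    if (scale == "linear" && any(v <= 0)) {
      bad <- which(v <= 0)[1]
      abort(sprintf("Non-positive linear value at row %d (gene '%s'), column '%s'.",
                    bad, df$gene_id[bad], names(df)[j]))
    }
  }
  if (scale == "linear") {
    df <- mutate(df, across(-"gene_id", log2))
    scale <- "log2"
  }
  structure(df, scale = scale, class = c("expr_tbl", class(df)))
}

#' @export
print.expr_tbl <- function(x, ...) {
  cat(sprintf("# Expression table: %d genes x %d samples (scale: %s)\n",
              nrow(x), ncol(x) - 1L, expr_scale(x)))
  NextMethod()
}

#' Intensity scale of an expression table
#' @param expr An `expr_tbl`.
#' @return `"log2"` or `"log2ratio"`.
#' @export
expr_scale <- function(expr) attr(expr, "scale") %||% "log2"

#' Numeric matrix view of an expression table
#' @param expr An `expr_tbl` (or any gene_id + samples data frame).
#' @return Numeric matrix, genes in rows (rownames = gene ids).
#' @export
expr_matrix <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$gene_id
  m
}

#' Sample descriptors of an expression table
#' @param expr An `expr_tbl`.
#' @return Tibble of parsed descriptors, one row per sample column, in column order.
#' @export
expr_samples <- function(expr) parse_sample_names(names(expr)[-1])

#' Read a tab-separated expression table
#'
#' Expects gene identifiers in the first column and a header of sample names
#' parseable by [parse_sample_names()]. Duplicate ids, non-numeric cells,
#' missing values, and non-positive values under `scale = "linear"` are load
#' errors reporting the offending coordinates.
#'
#' @param path Path to a TSV file.
#' @inheritParams as_expr
#' @return An `expr_tbl`.
#' @export
read_expression_table <- function(path, scale = c("log2", "linear", "log2ratio")) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  as_expr(df, scale = match.arg(scale))
}

#' Write an expression table as TSV with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records the intensity scale and shape so a
#' table can be reloaded without guessing its provenance.
#'
#' @param expr An `expr_tbl`.
#' @param path Output TSV path.
#' @param sidecar Write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path, sidecar = TRUE) {
  readr::write_tsv(as_tibble(expr), path, progress = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(scale = expr_scale(expr), n_genes = nrow(expr),
           n_samples = ncol(expr) - 1L),
      paste0(path, ".json"), auto_unbox = TRUE
    )
  }
  invisible(path)
}

#' Average biological replicates
#'
#' Collapses replicate columns to one column per (vineyard, year, stage)
#' group by the unweighted arithmetic mean on the log2 scale; output columns
#' are named without the replicate letter. Already-averaged input is returned
#' unchanged (the operation is idempotent).
#'
#' @param expr An `expr_tbl`.
#' @return An `expr_tbl` with one column per (vineyard, year, stage).
#' @export
average_replicates <- function(expr) {
  info <- expr_samples(expr)
  key <- paste0(info$vineyard, info$year, info$stage)
  m <- expr_matrix(expr)
  groups <- unique(key)
  avg <- vapply(groups, function(g) rowMeans(m[, key == g, drop = FALSE]),
                numeric(nrow(m)))
  if (is.null(dim(avg))) {
    avg <- matrix(avg, nrow = nrow(m), dimnames = list(NULL, groups))
  }
  out <- bind_cols(tibble(gene_id = expr$gene_id),
                   as_tibble(avg, .name_repair = "minimal"))
  names(out)[-1] <- groups
  as_expr(out, scale = if (expr_scale(expr) == "log2ratio") "log2ratio" else "log2")
}

#' Normalize ripening stages to veraison
#'
#' Converts intensities to log2 ratios against the veraison (stage 1)
#' baseline of the same vineyard and year: each stage-2/3 value becomes
#' `value - mean(stage-1 values of that vineyard and year)`. Stage-1 columns
#' are dropped and the result is tagged `log2ratio`.
#'
#' @param expr An `expr_tbl` containing stage-1 columns for every
#'   (vineyard, year) present.
#' @return An `expr_tbl` of stage-2/3 columns on the log2-ratio scale.
#' @export
normalize_to_veraison <- function(expr) {
  info <- expr_samples(expr)
  m <- expr_matrix(expr)
  vy <- paste0(info$vineyard, info$year)
  keep <- which(info$stage != 1L)
  if (length(keep) == 0) abort("No stage-2/3 columns to normalize.")
  out_m <- matrix(0, nrow(m), length(keep))
  for (i in seq_along(keep)) {
    j <- keep[i]
    base_cols <- which(vy == vy[j] & info$stage == 1L)
    if (length(base_cols) == 0) {
      abort(sprintf("No veraison (stage-1) columns for vineyard %s, year %s.",
                    info$vineyard[j], info$year[j]))
    }
    out_m[, i] <- m[, j] - rowMeans(m[, base_cols, drop = FALSE])
  }
  out <- bind_cols(tibble(gene_id = expr$gene_id),
                   as_tibble(out_m, .name_repair = "minimal"))
  names(out)[-1] <- info$sample[keep]
  as_expr(out, scale = "log2ratio")
}

#' Subset an expression table
#'
#' @param expr An `expr_tbl`.
#' @param genes Optional character vector of gene ids to keep (order preserved
#'   as in `expr`).
#' @param samples Optional character vector of sample names to keep.
#' @return An `expr_tbl`.
#' @export
expr_subset <- function(expr, genes = NULL, samples = NULL) {
  out <- expr
  if (!is.null(genes)) {
    missing <- setdiff(genes, out$gene_id)
    if (length(missing) > 0) {
      abort(sprintf("Unknown gene_id(s): %s", paste(head(missing, 5), collapse = ", ")))
    }
    out <- out[out$gene_id %in% genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, names(out)[-1])
    if (length(missing) > 0) {
      abort(sprintf("Unknown sample(s): %s", paste(head(missing, 5), collapse = ", ")))
    }
    out <- out[, c("gene_id", samples)]
  }
  as_expr(out, scale = expr_scale(expr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
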