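#' Specification for a synthetic plasticity study
#'
#' Describes a factorial berry-study design (vineyards x stages x replicates,
#' optionally x years) and the gene classes planted in it. Defaults emulate
#' the desk-scale study design this package targets: 11 vineyards, 3
#' developmental stages, 3 biological replicates, one season, 2,000 genes.
#'
#' Gene classes and their generative terms (all on the log2 scale):
#' \describe{
#'   \item{constitutive}{no design effect, tight replicate noise
#'     (`constitutive_noise_sd`), the intended reference genes;}
#'   \item{marker_up / marker_down}{monotone stage term
#'     `+/- stage_effect * (stage - 1)` shared by all vineyards;}
#'   \item{plastic}{vineyard-specific intercepts drawn
#'     `N(0, plastic_effect_sd^2)` per vineyard;}
#'   \item{year_effect}{year-specific intercepts drawn `N(0, year_effect^2)`
#'     per year (inert when `n_years = 1`);}
#'   \item{bimodal_low}{low-intensity genes whose per-sample values flip
#'     between two modes, `bimodal_low_mean` and
#'     `bimodal_low_mean + bimodal_gap` (balanced Bernoulli draw per gene
#'     and sample), emulating the array's low-signal bimodal artifact of
#'     probes fluctuating around the background level;}
#'   \item{background}{no design effect, ordinary replicate noise.}
#' }
#'
#' @param n_vineyards,n_stages,n_replicates,n_years Design dimensions.
#' @param n_constitutive,n_marker_up,n_marker_down,n_plastic,n_year_effect,n_bimodal_low,n_background
#'   Gene counts per class.
#' @param baseline_mean,baseline_sd Per-gene baseline distribution (log2).
#' @param stage_effect Log2 units per stage step for markers.
#' @param plastic_effect_sd Sd of vineyard-specific offsets (log2).
#' @param year_effect Sd of year-specific offsets (log2).
#' @param replicate_noise_sd Replicate noise sd (log2), all classes except
#'   constitutive.
#' @param constitutive_noise_sd Replicate noise sd for constitutive genes.
#' @param bimodal_low_mean Lower mode of the bimodal_low baseline mixture.
#' @param bimodal_gap Log2 separation of the two low-intensity modes.
#' @param plastic_stage_interaction If `TRUE`, plastic genes additionally get
#'   vineyard-specific slopes over stages (sd `plastic_effect_sd / 2`).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_vineyards = 11, n_stages = 3, n_replicates = 3,
                           n_years = 1,
                           n_constitutive = 150, n_marker_up = 100,
                           n_marker_down = 100, n_plastic = 150,
                           n_year_effect = 100, n_bimodal_low = 1000,
                           n_background = 400,
                           baseline_mean = 10, baseline_sd = 1,
                           stage_effect = 2, plastic_effect_sd = 1,
                           year_effect = 1.5,
                           replicate_noise_sd = 0.5,
                           constitutive_noise_sd = 0.1,
                           bimodal_low_mean = 2.5, bimodal_gap = 2.5,
                           plastic_stage_interaction = FALSE) {
  spec <- as.list(environment())
  counts <- unlist(spec[grep("^n_(constitutive|marker|plastic|year_effect|bimodal|background)", names(spec))])
  if (any(counts < 0)) abort("All gene-class counts must be >= 0.")
  sds <- c(baseline_sd, plastic_effect_sd, year_effect, replicate_noise_sd,
           constitutive_noise_sd)
  if (any(sds < 0)) abort("All sd parameters must be >= 0.")
  if ((n_marker_up + n_marker_down) > 0 && n_stages < 2) {
    abort("Markers require n_stages >= 2.")
  }
  if (n_vineyards < 1 || n_stages < 1 || n_replicates < 1 || n_years < 1) {
    abort("Design dimensions must be >= 1.")
  }
  structure(spec, class = "synthetic_spec")
}

# Vineyard codes: the 11 field codes first, then generated 2-letter codes.
vineyard_codes <- function(n) {
  base <- c("AM", "CS", "MN", "PSP", "VM", "GIV", "CC", "PM", "FA", "BA", "BM")
  if (n <= length(base)) return(base[seq_len(n)])
  extra <- apply(expand.grid(LETTERS, LETTERS)[, 2:1], 1, paste0, collapse = "")
  extra <- setdiff(extra, base)
  c(base, extra)[seq_len(n)]
}

#' Generate a synthetic expression dataset with ground truth
#'
#' Draws an expression table under the generative model of [synthetic_spec()]
#' together with a truth table mapping each gene to its planted class.
#' Identical `spec` and `seed` give bit-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed controlling every random draw.
#' @return A list with elements `expr` (an `expr_tbl`) and `truth` (tibble
#'   `gene_id`, `class`).
#' @export
generate_dataset <- function(spec = synthetic_spec(), seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  classes <- c(
    rep("constitutive", spec$n_constitutive),
    rep("marker_up", spec$n_marker_up),
    rep("marker_down", spec$n_marker_down),
    rep("plastic", spec$n_plastic),
    rep("year_effect", spec$n_year_effect),
    rep("bimodal_low", spec$n_bimodal_low),
    rep("background", spec$n_background)
  )
  n_genes <- length(classes)
  if (n_genes == 0) abort("Zero total genes requested.")
  design <- tidyr::expand_grid(
    vineyard = vineyard_codes(spec$n_vineyards),
    year = sprintf("%02d", 6 + seq_len(spec$n_years) - 1),
    stage = seq_len(spec$n_stages),
    replicate = LETTERS[seq_len(spec$n_replicates)]
  )
  n_samples <- nrow(design)
  if (n_samples == 0) abort("Zero samples in design.")
  gene_id <- sprintf("GENE%05d", seq_len(n_genes))

  set.seed(seed)
  baseline <- rnorm(n_genes, spec$baseline_mean, spec$baseline_sd)
  bi <- classes == "bimodal_low"
  baseline[bi] <- spec$bimodal_low_mean

  m <- matrix(baseline, n_genes, n_samples)
  # low-signal artifact: per-sample flips between the background mode and
  # the background + gap mode, the within-profile bimodality the intensity
  # filter screens for
  if (any(bi)) {
    m[bi, ] <- m[bi, ] +
      spec$bimodal_gap * matrix(rbinom(sum(bi) * n_samples, 1, 0.5),
                                sum(bi), n_samples)
  }

  stage_step <- matrix(design$stage - 1, n_genes, n_samples, byrow = TRUE)
  sign <- ifelse(classes == "marker_up", 1, ifelse(classes == "marker_down", -1, 0))
  m <- m + spec$stage_effect * sign * stage_step

  pl <- which(classes == "plastic")
  if (length(pl) > 0) {
    voff <- matrix(rnorm(length(pl) * spec$n_vineyards, 0, spec$plastic_effect_sd),
                   length(pl), spec$n_vineyards,
                   dimnames = list(NULL, vineyard_codes(spec$n_vineyards)))
    m[pl, ] <- m[pl, ] + voff[, design$vineyard, drop = FALSE]
    if (isTRUE(spec$plastic_stage_interaction)) {
      vslope <- matrix(rnorm(length(pl) * spec$n_vineyards, 0, spec$plastic_effect_sd / 2),
                       length(pl), spec$n_vineyards,
                       dimnames = list(NULL, vineyard_codes(spec$n_vineyards)))
      m[pl, ] <- m[pl, ] +
        vslope[, design$vineyard, drop = FALSE] * stage_step[pl, , drop = FALSE]
    }
  }

  ye <- which(classes == "year_effect")
  if (length(ye) > 0 && spec$n_years > 1) {
    years <- unique(design$year)
    yoff <- matrix(rnorm(length(ye) * length(years), 0, spec$year_effect),
                   length(ye), length(years), dimnames = list(NULL, years))
    m[ye, ] <- m[ye, ] + yoff[, design$year, drop = FALSE]
  }

  noise_sd <- ifelse(classes == "constitutive",
                     spec$constitutive_noise_sd, spec$replicate_noise_sd)
  m <- m + matrix(rnorm(n_genes * n_samples), n_genes, n_samples) * noise_sd

  colnames(m) <- encode_sample_names(design)
  expr <- as_expr(bind_cols(tibble(gene_id = gene_id),
                            as_tibble(m, .name_repair = "minimal")),
                  scale = "log2")
  list(expr = expr, truth = tibble(gene_id = gene_id, class = classes))
}
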