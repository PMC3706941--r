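#' Parse sample names of the vineyard/year/stage/replicate scheme
#'
#' Sample names follow the field scheme `<VINEYARD><YY><STAGE>[<REP>]`: a 2-3
#' letter uppercase vineyard code, a two-digit harvest-year token (e.g. `"08"`),
#' a developmental-stage digit (1 = veraison, 2 = mid-ripening, 3 = fully
#' ripe), and an optional biological-replicate letter `A`-`C`. A name without a
#' replicate letter denotes a replicate-averaged sample.
#'
#' @param x Character vector of sample names.
#' @return A tibble with columns `sample`, `vineyard`, `year`, `stage`
#'   (integer), `replicate` (`NA` when replicate-averaged).
#' @examples
#' parse_sample_names(c("FA081", "AM062B"))
#' @export
parse_sample_names <- function(x) {
  if (!is.character(x) || length(x) == 0) {
    abort("`x` must be a non-empty character vector of sample names.")
  }
  m <- regexec("^([A-Za-z]+)([0-9]+)([A-Za-z]?)$", x)
  parts <- regmatches(x, m)
  out <- purrr::map2(x, parts, function(name, p) {
    if (length(p) == 0) {
      abort(sprintf("Malformed sample name '%s': expected <VINEYARD><YY><STAGE>[<REP>].", name))
    }
    vineyard <- p[2]
    digits <- p[3]
    rep <- p[4]
    if (!grepl("^[A-Z]{2,3}$", vineyard)) {
      abort(sprintf("Sample name '%s': vineyard code '%s' must be 2-3 uppercase letters.", name, vineyard))
    }
    if (nchar(digits) != 3) {
      abort(sprintf("Sample name '%s': year token must be 2 digits followed by a 1-digit stage.", name))
    }
    year <- substr(digits, 1, 2)
    stage <- as.integer(substr(digits, 3, 3))
    if (!stage %in% 1:3) {
      abort(sprintf("Sample name '%s': stage %d invalid (must be 1-3).", name, stage))
    }
    if (nzchar(rep) && !rep %in% c("A", "B", "C")) {
      abort(sprintf("Sample name '%s': replicate '%s' invalid (must be A-C).", name, rep))
    }
    tibble(
      sample = name, vineyard = vineyard, year = year, stage = stage,
      replicate = if (nzchar(rep)) rep else NA_character_
    )
  })
  bind_rows(out)
}

#' Encode sample descriptors back into sample names
#'
#' Inverse of [parse_sample_names()]: `encode_sample_names(parse_sample_names(x))`
#' reproduces `x` for every valid name.
#'
#' @param desc A data frame with columns `vineyard`, `year`, `stage` and
#'   optionally `replicate` (`NA` for replicate-averaged samples).
#' @return Character vector of sample names.
#' @export
encode_sample_names <- function(desc) {
  stopifnot(is.data.frame(desc), all(c("vineyard", "year", "stage") %in% names(desc)))
  rep <- if ("replicate" %in% names(desc)) desc$replicate else rep(NA_character_, nrow(desc))
  rep[is.na(rep)] <- ""
  paste0(desc$vineyard, desc$year, desc$stage, rep)
}
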