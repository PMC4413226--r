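#' Squared correlation between posterior dosages and true genotypes
#'
#' The standard imputation-accuracy statistic: squared Pearson correlation
#' between the posterior expected alternative-allele dosage and the true
#' genotype (0/1/2).
#'
#' @param dosage Numeric vector of posterior dosages.
#' @param truth Integer vector of true genotypes in \{0, 1, 2\}.
#' @return r-squared in `[0, 1]`; `NA` (with a warning) when either vector is
#'   constant.
#' @export
dosage_r2 <- function(dosage, truth) {
  if (length(dosage) != length(truth)) rlang::abort("length mismatch")
  stopifnot(all(truth %in% 0:2))
  if (stats::var(truth) == 0 || stats::var(dosage) == 0) {
    rlang::warn("zero variance; r-squared undefined")
    return(NA_real_)
  }
  stats::cor(dosage, truth)^2
}

#' Hard-call concordance with the truth
#'
#' @param calls,truth Genotype vectors (0/1/2); `NA` calls count as
#'   discordant.
#' @return Fraction of individuals whose call equals the truth.
#' @export
call_concordance <- function(calls, truth) {
  if (length(calls) != length(truth)) rlang::abort("length mismatch")
  mean(!is.na(calls) & calls == truth)
}

#' Per-variant accuracy report with frequency and info stratification
#'
#' @param df Long tibble with one row per variant x individual:
#'   columns `variant`, `dosage`, `call`, `truth`, and per-variant `freq`
#'   and `info` (constant within a variant).
#' @param freq_breaks,info_breaks Bin edges for the stratified summary.
#' @return List with `per_variant` (r2 and concordance per variant) and
#'   `by_bin` (mean r2/concordance per frequency x info bin).
#' @export
concordance_report <- function(df,
                               freq_breaks = c(0, 0.001, 0.01, 0.05, 0.2, 0.5),
                               info_breaks = c(0, 0.4, 0.8, 1, Inf)) {
  df <- tibble::as_tibble(df)
  per_variant <- df |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(
      freq = dplyr::first(.data$freq),
      info = dplyr::first(.data$info),
      r2 = suppressWarnings(dosage_r2(.data$dosage, .data$truth)),
      concordance = call_concordance(.data$call, .data$truth),
      .groups = "drop"
    )
  by_bin <- per_variant |>
    dplyr::mutate(
      freq_bin = cut(.data$freq, freq_breaks, include.lowest = TRUE),
      info_bin = cut(.data$info, info_breaks, include.lowest = TRUE)
    ) |>
    dplyr::group_by(.data$freq_bin, .data$info_bin) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_r2 = mean(.data$r2, na.rm = TRUE),
                     mean_concordance = mean(.data$concordance),
                     .groups = "drop")
  structure(list(per_variant = per_variant, by_bin = by_bin),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d variants; mean r2 %.4f, mean concordance %.4f\n",
              nrow(x$per_variant),
              mean(x$per_variant$r2, na.rm = TRUE),
              mean(x$per_variant$concordance)))
  invisible(x)
}

# trim shared suffix then shared prefix (keeping >= 1 base), adjusting pos;
# left-alignment against the reference is assumed done upstream
normalize_allele <- function(pos, ref, alt) {
  rs <- strsplit(ref, "")[[1]]; as <- strsplit(alt, "")[[1]]
  while (length(rs) > 1 && length(as) > 1 && rs[length(rs)] == as[length(as)]) {
    rs <- rs[-length(rs)]; as <- as[-length(as)]
  }
  while (length(rs) > 1 && length(as) > 1 && rs[1] == as[1]) {
    rs <- rs[-1]; as <- as[-1]; pos <- pos + 1
  }
  list(pos = pos, ref = paste(rs, collapse = ""), alt = paste(as, collapse = ""))
}

site_keys <- function(sites) {
  norm <- purrr::pmap(list(sites$pos, sites$ref, sites$alt), normalize_allele)
  paste(sites$chrom,
        vapply(norm, `[[`, 0, "pos"),
        vapply(norm, `[[`, "", "ref"),
        vapply(norm, `[[`, "", "alt"))
}

#' Fraction of variants present in a reference site catalogue
#'
#' A variant counts as present when the catalogue holds a record at the same
#' position with the same alleles (after trimming shared allele context, so
#' redundant indel representations match). Variants with undetermined
#' polarization carry no DAF and are excluded.
#'
#' @param sites Tibble with `chrom`, `pos`, `ref`, `alt`, `daf` and
#'   optionally `type` (derived from the alleles when absent).
#' @param catalogue Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param daf_breaks DAF bin edges.
#' @return Tibble with one row per variant type x DAF bin: `n`, `n_present`,
#'   `fraction`.
#' @export
catalogue_overlap <- function(sites, catalogue,
                              daf_breaks = c(0, 0.005, 0.02, 0.1, 0.5, 1)) {
  sites <- tibble::as_tibble(sites)
  if (!"type" %in% names(sites)) sites$type <- variant_type(sites$ref, sites$alt)
  sites <- sites[!is.na(sites$daf), ]
  if (nrow(sites) == 0) {
    return(tibble::tibble(type = character(), daf_bin = factor(),
                          n = integer(), n_present = integer(),
                          fraction = numeric()))
  }
  cat_keys <- if (nrow(catalogue) > 0) site_keys(tibble::as_tibble(catalogue)) else character(0)
  sites$present <- site_keys(sites) %in% cat_keys
  sites$daf_bin <- cut(sites$daf, daf_breaks, include.lowest = TRUE)
  sites |>
    dplyr::group_by(.data$type, .data$daf_bin) |>
    dplyr::summarise(n = dplyr::n(), n_present = sum(.data$present),
                     fraction = mean(.data$present), .groups = "drop")
}

#' Indel length spectrum
#'
#' Signed indel lengths (insertions positive, deletions negative) counted
#' inside and outside protein-coding regions, with the in-frame
#' (multiple-of-three) / frameshift split.
#'
#' @param indels Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param coding_mask Optional `GRanges` of protein-coding regions; without
#'   it everything is "outside".
#' @return Tibble with one row per (length, region): `length`, `coding`,
#'   `frame` (`"in_frame"`/`"frameshift"`), `n`.
#' @export
indel_length_spectrum <- function(indels, coding_mask = NULL) {
  indels <- tibble::as_tibble(indels)
  len <- nchar(indels$alt) - nchar(indels$ref)
  if (any(len == 0)) rlang::abort("zero-length record is not an indel")
  if (any(abs(len) > 60)) rlang::abort("indel length outside [1, 60]")
  coding <- span_masked(indels$chrom, indels$pos, indels$ref, coding_mask)
  tibble::tibble(
    length = len,
    coding = ifelse(coding, "inside_coding", "outside_coding"),
    frame = ifelse(len %% 3 == 0, "in_frame", "frameshift")
  ) |>
    dplyr::count(.data$length, .data$coding, .data$frame, name = "n")
}
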