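#' Severity-ordered impact classes
#'
#' @return The class levels in decreasing severity:
#'   `LoF`, `MODERATE`, `LOW`, `OTHER`.
#' @export
impact_levels <- function() c("LoF", "MODERATE", "LOW", "OTHER")

#' Consequence-term to impact-class map
#'
#' Maps Sequence Ontology consequence terms (snake_case, VEP vocabulary) to
#' the four impact classes. Frameshift, essential-splice, stop gained/lost
#' and initiator-codon changes are loss-of-function; missense, in-frame
#' indels and splice-region changes are MODERATE; synonymous, stop-retained
#' and UTR changes are LOW; intronic, intergenic and up/downstream changes
#' are OTHER.
#'
#' @return Tibble with columns `term` and `impact` (ordered factor).
#' @export
impact_map <- function() {
  tbl <- tibble::tribble(
    ~term,                       ~impact,
    "frameshift_variant",        "LoF",
    "splice_acceptor_variant",   "LoF",
    "splice_donor_variant",      "LoF",
    "stop_gained",               "LoF",
    "stop_lost",                 "LoF",
    "initiator_codon_variant",   "LoF",
    "missense_variant",          "MODERATE",
    "inframe_insertion",         "MODERATE",
    "inframe_deletion",          "MODERATE",
    "splice_region_variant",     "MODERATE",
    "synonymous_variant",        "LOW",
    "stop_retained_variant",     "LOW",
    "3_prime_UTR_variant",       "LOW",
    "5_prime_UTR_variant",       "LOW",
    "intron_variant",            "OTHER",
    "intergenic_variant",        "OTHER",
    "upstream_gene_variant",     "OTHER",
    "downstream_gene_variant",   "OTHER"
  )
  tbl$impact <- factor(tbl$impact, levels = impact_levels(), ordered = TRUE)
  tbl
}

the_warned_terms <- new.env(parent = emptyenv())

#' Most severe impact class across a variant's consequence terms
#'
#' A variant annotated against several transcripts can carry several
#' consequence terms; it is assigned the most severe applicable class.
#' Unrecognised terms fall back to `OTHER` with a warning issued once per
#' term per session; a variant with no terms at all defaults to intergenic,
#' hence `OTHER`.
#'
#' @param terms Character vector of consequence terms for one variant.
#' @param map Term table, see [impact_map()].
#' @return Impact class (ordered factor of length 1).
#' @export
most_severe_impact <- function(terms, map = impact_map()) {
  lv <- levels(map$impact)
  terms <- terms[!is.na(terms) & terms != ""]
  if (length(terms) == 0) {
    return(factor("OTHER", levels = lv, ordered = TRUE))
  }
  idx <- match(terms, map$term)
  unknown <- unique(terms[is.na(idx)])
  for (u in unknown) {
    if (is.null(the_warned_terms[[u]])) {
      the_warned_terms[[u]] <- TRUE
      rlang::warn(sprintf("unrecognised consequence term \"%s\"; classed as OTHER", u))
    }
  }
  classes <- as.character(map$impact[idx])
  classes[is.na(classes)] <- "OTHER"
  factor(lv[min(match(classes, lv))], levels = lv, ordered = TRUE)
}

#' Classify a site table by impact
#'
#' @param sites Tibble with a `consequences` column: either a list-column of
#'   character vectors or a character column with `&`-separated terms.
#' @param map Term table, see [impact_map()].
#' @return `sites` with an added ordered-factor `impact` column.
#' @export
classify_impacts <- function(sites, map = impact_map()) {
  sites <- tibble::as_tibble(sites)
  cons <- sites$consequences
  if (!is.list(cons)) cons <- strsplit(as.character(cons), "&", fixed = TRUE)
  sites$impact <- do.call(c, lapply(cons, most_severe_impact, map = map))
  sites
}

#' Is a SNP a transition?
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine substitutions:
#' allele pairs \{A, G\} and \{C, T\}. All other substitutions are
#' transversions.
#'
#' @param ref,alt Single-base alleles (vectorised).
#' @return Logical vector.
#' @export
is_transition <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(nchar(ref) != 1 | nchar(alt) != 1)) {
    rlang::abort("transition/transversion is defined for single-base alleles only")
  }
  pair <- paste(pmin(ref, alt), pmax(ref, alt))
  pair %in% c("A G", "C T")
}

#' Transition/transversion ratio, optionally stratified
#'
#' @param snps Tibble with `ref` and `alt` single-base allele columns.
#' @param by Optional name of a stratification column in `snps`.
#' @return Tibble with one row per stratum: `n_ts`, `n_tv`, `tstv`
#'   (`Inf` when a stratum has transitions but no transversions, `NA` when
#'   empty).
#' @export
tstv_ratio <- function(snps, by = NULL) {
  snps <- tibble::as_tibble(snps)
  ts <- is_transition(snps$ref, snps$alt)
  strat <- if (is.null(by)) rep("all", nrow(snps)) else as.character(snps[[by]])
  out <- tibble::tibble(stratum = strat, ts = ts) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(n_ts = sum(.data$ts), n_tv = sum(!.data$ts),
                     .groups = "drop") |>
    dplyr::mutate(tstv = dplyr::case_when(
      .data$n_ts + .data$n_tv == 0 ~ NA_real_,
      .data$n_tv == 0 ~ Inf,
      .default = .data$n_ts / .data$n_tv
    ))
  out
}

#' Enumerate all single-base substitutions of the stop codons
#'
#' Every substitution of one base in TAA, TAG and TGA, flagged by whether the
#' mutated codon is still a stop (a stop-retained change). Stop-retained
#' changes are obligate transitions, which this enumeration makes checkable.
#'
#' @return Tibble with `codon`, `position`, `ref`, `alt`, `new_codon`,
#'   `stop_retained`.
#' @export
enumerate_stop_codon_snvs <- function() {
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (codon in stops) {
    cc <- strsplit(codon, "")[[1]]
    for (p in 1:3) {
      for (b in setdiff(bases, cc[p])) {
        nc <- cc; nc[p] <- b
        rows[[length(rows) + 1]] <- tibble::tibble(
          codon = codon, position = p, ref = cc[p], alt = b,
          new_codon = paste(nc, collapse = ""),
          stop_retained = paste(nc, collapse = "") %in% stops
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
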