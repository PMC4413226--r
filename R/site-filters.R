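#' Default hard-filter rule set
#'
#' One row per rule. SNPs fail on QD < 2, MQ < 40, FS > 60,
#' HaplotypeScore > 13, MQRankSum < -12.5 or ReadPosRankSum < -8; indels on
#' QD < 2, FS > 200 or ReadPosRankSum < -20 (the GATK Best Practices hard
#' thresholds). Both types additionally fail on DP > 110000, AN < 4200,
#' HW < 1e-7, SI > 1.4, and on low information: SI < 0.6 for SNPs,
#' SI < 0.9 for indels. Inequalities are strict: a value exactly at a
#' threshold passes. A missing annotation cannot fail its rule.
#'
#' @return Tibble with columns `name` (reported on failure), `key`
#'   (annotation column), `op` (`"<"` fails when value < threshold, `">"`
#'   fails when value > threshold), `threshold`, `type` (`"snp"` or
#'   `"indel"`).
#' @export
filter_rules <- function() {
  tibble::tribble(
    ~name,            ~key,              ~op, ~threshold, ~type,
    "QD",             "QD",              "<",        2.0, "snp",
    "MQ",             "MQ",              "<",       40.0, "snp",
    "FS",             "FS",              ">",       60.0, "snp",
    "HaplotypeScore", "HaplotypeScore",  ">",       13.0, "snp",
    "MQRankSum",      "MQRankSum",       "<",      -12.5, "snp",
    "ReadPosRankSum", "ReadPosRankSum",  "<",       -8.0, "snp",
    "QD",             "QD",              "<",        2.0, "indel",
    "FS",             "FS",              ">",      200.0, "indel",
    "ReadPosRankSum", "ReadPosRankSum",  "<",      -20.0, "indel",
    "DP",             "DP",              ">",   110000.0, "snp",
    "DP",             "DP",              ">",   110000.0, "indel",
    "AN",             "AN",              "<",     4200.0, "snp",
    "AN",             "AN",              "<",     4200.0, "indel",
    "HW",             "HW",              "<",       1e-7, "snp",
    "HW",             "HW",              "<",       1e-7, "indel",
    "SI_high",        "SI",              ">",        1.4, "snp",
    "SI_high",        "SI",              ">",        1.4, "indel",
    "SI_low",         "SI",              "<",        0.6, "snp",
    "SI_low",         "SI",              "<",        0.9, "indel"
  )
}

#' Classify variant sites against the hard-filter rules
#'
#' Evaluates every rule applicable to each site's variant type and tests the
#' site's reference span against the simple-repeat mask. A site passes when
#' no rule fails and it is not repeat-masked. Rules are independent, so the
#' failed-rule set does not depend on rule order.
#'
#' @param sites Tibble with `chrom`, `pos`, `ref`, `alt` and any of the
#'   annotation columns named in `rules$key` (missing columns or `NA` values
#'   simply cannot fail). A `type` column (`"snp"`/`"indel"`) is derived from
#'   the alleles when absent.
#' @param rules Rule table, see [filter_rules()].
#' @param repeat_mask Optional `GRanges` mask from [build_repeat_mask()].
#' @return `sites` with added columns `failed_rules` (character, rule names
#'   joined by `";"`, `""` when clean), `masked_repeat` and `pass`.
#' @export
classify_sites <- function(sites, rules = filter_rules(), repeat_mask = NULL) {
  sites <- tibble::as_tibble(sites)
  if (!"type" %in% names(sites)) sites$type <- variant_type(sites$ref, sites$alt)
  if (!all(sites$type %in% c("snp", "indel"))) {
    rlang::abort("unknown variant type; expected \"snp\" or \"indel\"")
  }
  failed <- vector("list", nrow(sites))
  for (j in seq_along(failed)) failed[[j]] <- character(0)
  for (r in seq_len(nrow(rules))) {
    key <- rules$key[r]
    if (!key %in% names(sites)) next
    v <- sites[[key]]
    applicable <- sites$type == rules$type[r] & !is.na(v)
    hit <- applicable &
      if (rules$op[r] == "<") v < rules$threshold[r] else v > rules$threshold[r]
    hit[is.na(hit)] <- FALSE
    for (j in which(hit)) failed[[j]] <- union(failed[[j]], rules$name[r])
  }
  sites$failed_rules <- vapply(failed, paste, "", collapse = ";")
  sites$masked_repeat <- span_masked(sites$chrom, sites$pos, sites$ref, repeat_mask)
  sites$pass <- sites$failed_rules == "" & !sites$masked_repeat
  sites
}

#' Derive the variant type from the alleles
#'
#' @param ref,alt Allele strings.
#' @return `"snp"` when both alleles are single bases, `"indel"` otherwise.
#' @export
variant_type <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "snp", "indel")
}

#' Per-rule failure tally
#'
#' @param classified Output of [classify_sites()].
#' @return Tibble with `rule` and `n_failed`, plus rows for repeat masking
#'   and overall passes.
#' @export
filter_tally <- function(classified) {
  fr <- unlist(strsplit(classified$failed_rules[classified$failed_rules != ""], ";"))
  tally <- tibble::tibble(rule = names(table(fr)),
                          n_failed = as.integer(table(fr)))
  dplyr::bind_rows(
    tally,
    tibble::tibble(rule = "repeat_mask",
                   n_failed = sum(classified$masked_repeat)),
    tibble::tibble(rule = "(pass)", n_failed = sum(classified$pass))
  )
}

#' Total number of chromosomes in called genotypes
#'
#' The AN annotation: two alleles per non-missing diploid genotype, the
#' quantity the AN filter rule bounds from below.
#'
#' @param genotypes Vector of per-individual genotypes; `NA` means no call.
#' @return Integer allele count.
#' @export
allele_number <- function(genotypes) {
  2L * sum(!is.na(genotypes))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the probability
#' of each possible heterozygote count under random pairing of alleles is
#' computed, and the two-sided p-value is the total probability of
#' configurations no more likely than the observed one.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total > 0).
#' @return Two-sided exact p-value; 1 for monomorphic samples.
#' @export
hardy_weinberg_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) rlang::abort("empty sample")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  lp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  sum(p[p <= obs * (1 + 1e-9)])
}
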