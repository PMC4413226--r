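#' Polarize a SNP against the inferred ancestral base
#'
#' Compares the ancestral base at the SNP position with the two alleles.
#' `"reference_ancestral"` means the alternative allele is derived,
#' `"alternative_ancestral"` means the reference allele is derived; anything
#' else (ancestor N, gap, missing, or a third base) is `"undetermined"`.
#'
#' Ancestor FASTA files often encode call confidence by case; by default both
#' cases count as calls, `high_confidence_only = TRUE` accepts uppercase
#' only.
#'
#' @param ref,alt,ancestral Character vectors (recycled) of the reference
#'   allele, the alternative allele, and the ancestral base.
#' @param high_confidence_only If `TRUE`, lowercase ancestral bases give
#'   `"undetermined"`.
#' @return Character vector of polarization states.
#' @export
polarize_snp <- function(ref, alt, ancestral, high_confidence_only = FALSE) {
  n <- max(length(ref), length(alt), length(ancestral))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  anc_raw <- rep_len(ancestral, n)
  low_conf <- anc_raw %in% c("a", "c", "g", "t")
  anc <- toupper(anc_raw)
  out <- rep("undetermined", n)
  out[!is.na(anc) & anc == ref] <- "reference_ancestral"
  out[!is.na(anc) & anc == alt] <- "alternative_ancestral"
  if (high_confidence_only) out[low_conf] <- "undetermined"
  out
}

#' Polarize an indel from aligned ancestor/human windows
#'
#' The two windows are gap-aligned sequences of equal length spanning 5 bp
#' plus the indel length on each side of the indel. Mismatches are counted
#' only at columns where both sequences have a base, so the indel site itself
#' (a gap run in one sequence) never counts as a mismatch; an ancestral N at
#' a compared column counts as a mismatch.
#'
#' Decision rule: if the two windows contain the same number of bases and at
#' most one mismatch, the reference allele is ancestral. If the base-count
#' difference equals the indel length with at most one flanking mismatch —
#' and, for insertions, the ancestor's extra bases equal the inserted
#' sequence exactly — the alternative allele is ancestral. Every other case
#' is undetermined.
#'
#' @param human_window,ancestral_window Aligned sequence windows (strings,
#'   `-` for gaps). An empty or all-N ancestral window is undetermined.
#' @param indel_len Length difference between the alleles, in `[1, 60]`.
#' @param type `"insertion"` or `"deletion"` (relative to the reference).
#' @param insert_seq For insertions, the inserted bases (required to call the
#'   alternative allele ancestral).
#' @return A polarization state string.
#' @export
polarize_indel <- function(human_window, ancestral_window, indel_len,
                           type = c("deletion", "insertion"),
                           insert_seq = NULL) {
  type <- match.arg(type)
  stopifnot(indel_len >= 1, indel_len <= 60)
  if (is.na(ancestral_window) || nchar(ancestral_window) == 0) {
    return("undetermined")
  }
  hc <- strsplit(toupper(human_window), "")[[1]]
  ac <- strsplit(toupper(ancestral_window), "")[[1]]
  if (length(hc) != length(ac)) {
    rlang::abort("aligned windows must have equal length")
  }
  h_base <- hc != "-"
  a_base <- ac != "-"
  if (all(ac[a_base] == "N")) return("undetermined")
  if (sum(h_base) < 10) {
    rlang::warn("window shorter than the required span; state undetermined")
    return("undetermined")
  }
  both <- h_base & a_base
  mismatches <- sum(hc[both] != ac[both] | ac[both] == "N")
  diff_bases <- abs(sum(h_base) - sum(a_base))

  if (diff_bases == 0 && mismatches <= 1) {
    return("reference_ancestral")
  }
  if (diff_bases == indel_len && mismatches <= 1) {
    if (type == "deletion") {
      return("alternative_ancestral")
    }
    # insertion: ancestor must carry the insert itself — the bases the
    # ancestor has where the (reference-based) human window has gaps
    extra <- ac[a_base & !h_base]
    if (!is.null(insert_seq) &&
        paste(extra, collapse = "") == toupper(insert_seq)) {
      return("alternative_ancestral")
    }
    return("undetermined")
  }
  "undetermined"
}

#' Derived allele frequency from the polarization state
#'
#' @param alt_freq Alternative-allele frequency in `[0, 1]` (vectorised).
#' @param state Polarization state(s) as returned by [polarize_snp()] /
#'   [polarize_indel()].
#' @return DAF: `alt_freq` when the reference allele is ancestral,
#'   `1 - alt_freq` when the alternative is ancestral, `NA` when
#'   undetermined.
#' @export
derived_allele_frequency <- function(alt_freq, state) {
  stopifnot(all(alt_freq >= 0 & alt_freq <= 1, na.rm = TRUE))
  dplyr::case_when(
    state == "reference_ancestral" ~ alt_freq,
    state == "alternative_ancestral" ~ 1 - alt_freq,
    .default = NA_real_
  )
}

#' Read toy ancestor alignment windows
#'
#' Tab-separated exchange format standing in for MAF-derived extracts:
#' columns `chrom`, `pos`, `type`, `indel_len`, `human_window`,
#' `ancestral_window`, `insert_seq` (empty for deletions).
#'
#' @param path Path to the TSV file.
#' @return Tibble of windows.
#' @export
read_ancestor_windows <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    type = readr::col_character(), indel_len = readr::col_integer(),
    human_window = readr::col_character(),
    ancestral_window = readr::col_character(),
    insert_seq = readr::col_character()
  ), na = character())
}

#' Polarize a table of indel windows
#'
#' @param windows Tibble as from [read_ancestor_windows()].
#' @return `windows` with an added `state` column.
#' @export
polarize_windows <- function(windows) {
  windows <- tibble::as_tibble(windows)
  windows$state <- purrr::pmap_chr(
    windows[, c("human_window", "ancestral_window", "indel_len", "type",
                "insert_seq")],
    function(human_window, ancestral_window, indel_len, type, insert_seq) {
      polarize_indel(human_window, ancestral_window, indel_len, type,
                     insert_seq = if (identical(insert_seq, "")) NULL else insert_seq)
    })
  windows
}
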