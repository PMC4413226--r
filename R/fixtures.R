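# Engineered toy inputs: every filter rule violated exactly once, every
# polarization branch covered, every consequence term present once.

baseline_annotations <- function() {
  c(QD = 10, MQ = 60, FS = 10, HaplotypeScore = 2, MQRankSum = 0,
    ReadPosRankSum = 0, DP = 50000, AN = 5272, HW = 0.5, SI = 1.0)
}

#' Write deterministic toy fixtures
#'
#' Produces small plain-text inputs that exercise every code path: a filter
#' VCF with 16 records (14 engineered to violate exactly one rule each — six
#' SNP-specific, three indel-specific, five shared — and two clean), a SNP
#' ancestral-state table, indel ancestor alignment windows covering the
#' reference-ancestral / alternative-ancestral / undetermined branches for
#' insertions and deletions, a tandem-repeat BED, a consequence-term VCF with
#' every supported term once, and a site catalogue containing a known subset
#' of the filter VCF records.
#'
#' @param dir Directory to write into (created if needed).
#' @return Named list of file paths, invisibly, with the expectation tables
#'   as attributes (`filter_expect`, `polarization_expect`).
#' @export
make_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- baseline_annotations()

  # one record per engineered rule violation; `value` replaces the baseline
  plan <- tibble::tribble(
    ~rule,            ~vtype,  ~key,              ~value,
    "QD",             "snp",   "QD",              1.9,
    "MQ",             "snp",   "MQ",              39.0,
    "FS",             "snp",   "FS",              100.0,
    "HaplotypeScore", "snp",   "HaplotypeScore",  14.0,
    "MQRankSum",      "snp",   "MQRankSum",       -13.0,
    "ReadPosRankSum", "snp",   "ReadPosRankSum",  -9.0,
    "QD",             "indel", "QD",              1.9,
    "FS",             "indel", "FS",              250.0,
    "ReadPosRankSum", "indel", "ReadPosRankSum",  -21.0,
    "DP",             "snp",   "DP",              120000.0,
    "AN",             "snp",   "AN",              4000.0,
    "HW",             "indel", "HW",              1e-8,
    "SI_high",        "snp",   "SI",              1.5,
    "SI_low",         "indel", "SI",              0.7,
    NA,               "snp",   NA,                NA,
    NA,               "indel", NA,                NA
  )
  recs <- character(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    ann <- base
    if (!is.na(plan$key[i])) ann[plan$key[i]] <- plan$value[i]
    ref <- if (plan$vtype[i] == "snp") "A" else "ATG"
    alt <- if (plan$vtype[i] == "snp") "G" else "A"
    vals <- vapply(ann, function(x) format(x, scientific = FALSE, trim = TRUE),
                   "")
    info <- paste(sprintf("%s=%s", names(ann), vals), collapse = ";")
    recs[i] <- paste("chr1", 1000 * i, sprintf("site%02d", i), ref, alt,
                     "100", ".", info, sep = "\t")
  }
  vcf_path <- file.path(dir, "filter.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            names(base), names(base)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  ), vcf_path)
  cat(paste(recs, collapse = "\n"), "\n", sep = "", file = vcf_path, append = TRUE)

  # SNP ancestral states: one per branch
  snp_path <- file.path(dir, "snp_ancestral.tsv")
  snp_tbl <- tibble::tribble(
    ~chrom, ~pos, ~ref, ~alt, ~ancestral, ~expect,
    "chr1", 100L, "A", "G", "A", "reference_ancestral",
    "chr1", 200L, "A", "G", "G", "alternative_ancestral",
    "chr1", 300L, "A", "G", "N", "undetermined"
  )
  readr::write_tsv(snp_tbl, snp_path)

  # indel ancestor windows: branches x {insertion, deletion}
  flank_l <- "ACGTG"; flank_r <- "TTACG"
  del_ref <- "CA"   # deleted bases (length 2)
  ins_seq <- "GG"   # inserted bases (length 2)
  win_tbl <- tibble::tribble(
    ~chrom, ~pos, ~type, ~indel_len, ~human_window, ~ancestral_window, ~insert_seq, ~expect,
    # deletion, ancestor == reference (carries the bases): ref ancestral
    "chr1", 500L, "deletion", 2L,
    paste0(flank_l, del_ref, flank_r), paste0(flank_l, del_ref, flank_r), "",
    "reference_ancestral",
    # deletion, ancestor lacks the bases: alternative ancestral
    "chr1", 510L, "deletion", 2L,
    paste0(flank_l, del_ref, flank_r), paste0(flank_l, "--", flank_r), "",
    "alternative_ancestral",
    # deletion, two flanking mismatches: undetermined
    "chr1", 520L, "deletion", 2L,
    paste0(flank_l, del_ref, flank_r), paste0("TTGTG", del_ref, flank_r), "",
    "undetermined",
    # insertion, ancestor matches the reference (no insert): ref ancestral
    "chr1", 530L, "insertion", 2L,
    paste0(flank_l, flank_r), paste0(flank_l, flank_r), ins_seq,
    "reference_ancestral",
    # insertion, ancestor carries the insert exactly: alternative ancestral
    "chr1", 540L, "insertion", 2L,
    paste0(flank_l, "--", flank_r), paste0(flank_l, ins_seq, flank_r), ins_seq,
    "alternative_ancestral",
    # insertion, ancestor has extra bases that do not match the insert
    "chr1", 550L, "insertion", 2L,
    paste0(flank_l, "--", flank_r), paste0(flank_l, "CC", flank_r), ins_seq,
    "undetermined"
  )
  win_path <- file.path(dir, "ancestor_windows.tsv")
  readr::write_tsv(win_tbl, win_path)

  # tandem-repeat intervals (BED, 0-based half-open)
  bed_path <- file.path(dir, "trf.bed")
  writeLines(c("chr1\t1990\t2010\ttrf1", "chr1\t5000\t5100\ttrf2"), bed_path)

  # consequence-term fixture: every supported term once
  term_path <- file.path(dir, "consequence_terms.tsv")
  readr::write_tsv(impact_map(), term_path)

  # catalogue holding a fixed subset of the filter VCF sites
  cat_path <- file.path(dir, "catalogue.tsv")
  cat_tbl <- tibble::tibble(
    chrom = "chr1", pos = 1000L * c(1L, 5L, 15L),
    ref = c("A", "A", "A"), alt = c("G", "G", "G")
  )
  readr::write_tsv(cat_tbl, cat_path)

  paths <- list(filter_vcf = vcf_path, snp_ancestral = snp_path,
                ancestor_windows = win_path, trf_bed = bed_path,
                consequence_terms = term_path, catalogue = cat_path)
  attr(paths, "filter_expect") <- plan
  attr(paths, "polarization_expect") <- win_tbl
  invisible(paths)
}
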