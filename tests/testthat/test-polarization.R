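test_that("SNP polarization follows the ancestral-base comparison", {
  expect_equal(polarize_snp("A", "G", "A"), "reference_ancestral")
  expect_equal(polarize_snp("A", "G", "G"), "alternative_ancestral")
  expect_equal(polarize_snp("A", "G", "N"), "undetermined")
  expect_equal(polarize_snp("A", "G", "C"), "undetermined")
  expect_equal(polarize_snp("A", "G", "-"), "undetermined")
  expect_equal(polarize_snp("A", "G", NA), "undetermined")

  # lowercase ancestors count by default, not in high-confidence mode
  expect_equal(polarize_snp("A", "G", "a"), "reference_ancestral")
  expect_equal(polarize_snp("A", "G", "a", high_confidence_only = TRUE),
               "undetermined")

  # swapping ref/alt swaps the two determinate outcomes; repolarizing is
  # idempotent
  withr::with_seed(2, {
    for (i in 1:20) {
      al <- sample(c("A", "C", "G", "T"), 2)
      anc <- sample(c("A", "C", "G", "T", "N"), 1)
      s1 <- polarize_snp(al[1], al[2], anc)
      s2 <- polarize_snp(al[2], al[1], anc)
      expect_equal(s1, polarize_snp(al[1], al[2], anc))
      flipped <- c(reference_ancestral = "alternative_ancestral",
                   alternative_ancestral = "reference_ancestral",
                   undetermined = "undetermined")
      expect_equal(s2, unname(flipped[s1]))
    }
  })
})

test_that("indel polarization implements the window decision rules", {
  fl <- "ACGTG"; fr <- "TTACG"
  # deletion of AC: ancestor identical to the reference window
  expect_equal(polarize_indel(paste0(fl, "AC", fr), paste0(fl, "AC", fr),
                              2, "deletion"), "reference_ancestral")
  # one flanking mismatch is still tolerated
  anc1 <- paste0("CCGTG", "AC", fr)
  expect_equal(polarize_indel(paste0(fl, "AC", fr), anc1, 2, "deletion"),
               "reference_ancestral")
  # ancestor lacking exactly the deleted bases
  expect_equal(polarize_indel(paste0(fl, "AC", fr), paste0(fl, "--", fr),
                              2, "deletion"), "alternative_ancestral")
  # two flanking mismatches: undetermined either way
  anc2 <- paste0("CAGTG", "AC", fr)
  expect_equal(polarize_indel(paste0(fl, "AC", fr), anc2, 2, "deletion"),
               "undetermined")
  expect_equal(polarize_indel(paste0(fl, "AC", fr), paste0("CAGTG", "--", fr),
                              2, "deletion"), "undetermined")
  # base-count difference unequal to the indel length: undetermined
  expect_equal(polarize_indel(paste0(fl, "AC", fr), paste0(fl, "-C", fr),
                              2, "deletion"), "undetermined")

  # insertions: the ancestor's extra bases must equal the insert exactly
  expect_equal(polarize_indel(paste0(fl, "--", fr), paste0(fl, "GG", fr),
                              2, "insertion", insert_seq = "GG"),
               "alternative_ancestral")
  expect_equal(polarize_indel(paste0(fl, "--", fr), paste0(fl, "GC", fr),
                              2, "insertion", insert_seq = "GG"),
               "undetermined")
  expect_equal(polarize_indel(paste0(fl, fr), paste0(fl, fr),
                              2, "insertion", insert_seq = "GG"),
               "reference_ancestral")

  # missing or unusable ancestral window
  expect_equal(polarize_indel(paste0(fl, "AC", fr), NA, 2, "deletion"),
               "undetermined")
  expect_equal(polarize_indel(paste0(fl, "AC", fr),
                              paste(rep("N", 12), collapse = ""),
                              2, "deletion"), "undetermined")
  expect_warning(
    st <- polarize_indel("ACG", "ACG", 1, "deletion"), "span")
  expect_equal(st, "undetermined")
})

test_that("planted mismatch counts decide recoverability exactly", {
  fl <- "ACGTG"; fr <- "TTACG"
  mutate_flank <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    # mutate the first k flank positions to a different base
    for (i in seq_len(k)) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  for (mism in 0:3) {
    # deletion, ancestor = reference branch
    anc <- paste0(mutate_flank(fl, mism), "AC", fr)
    st <- polarize_indel(paste0(fl, "AC", fr), anc, 2, "deletion")
    expect_equal(st, if (mism <= 1) "reference_ancestral" else "undetermined")
    # deletion, ancestor-deleted branch
    anc <- paste0(mutate_flank(fl, mism), "--", fr)
    st <- polarize_indel(paste0(fl, "AC", fr), anc, 2, "deletion")
    expect_equal(st, if (mism <= 1) "alternative_ancestral" else "undetermined")
    # insertion carrying the exact insert
    anc <- paste0(mutate_flank(fl, mism), "GG", fr)
    st <- polarize_indel(paste0(fl, "--", fr), anc, 2, "insertion",
                         insert_seq = "GG")
    expect_equal(st, if (mism <= 1) "alternative_ancestral" else "undetermined")
  }
})

test_that("derived allele frequency flips with the polarization state", {
  expect_equal(derived_allele_frequency(0.02, "reference_ancestral"), 0.02)
  expect_equal(derived_allele_frequency(0.02, "alternative_ancestral"), 0.98)
  expect_true(is.na(derived_allele_frequency(0.02, "undetermined")))
  # vectorised over a site table; undetermined sites drop out of DAF tallies
  daf <- derived_allele_frequency(
    c(0.1, 0.2, 0.3),
    c("reference_ancestral", "undetermined", "alternative_ancestral"))
  expect_equal(daf, c(0.1, NA, 0.7))
  expect_equal(sum(!is.na(daf)), 2)
})

test_that("window tables round-trip and polarize in bulk", {
  dir <- withr::local_tempdir()
  paths <- make_fixtures(dir)
  win <- read_ancestor_windows(paths$ancestor_windows)
  expect_equal(nrow(win), 6)
  out <- polarize_windows(win)
  expect_equal(out$state, attr(paths, "polarization_expect")$expect)
})
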