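base_site <- function(...) {
  tibble::tibble(chrom = "chr1", pos = 1000L, ref = "A", alt = "G",
                 QD = 10, MQ = 60, FS = 10, HaplotypeScore = 2,
                 MQRankSum = 0, ReadPosRankSum = 0, DP = 50000, AN = 5272,
                 HW = 0.5, SI = 1.0) |>
    dplyr::mutate(...)
}

failed_set <- function(classified) {
  strsplit(classified$failed_rules, ";")[[1]]
}

test_that("type-specific thresholds fire exactly as printed", {
  # QD just under the bound fails the QD rule alone; at the bound passes
  expect_equal(failed_set(classify_sites(base_site(QD = 1.9))), "QD")
  expect_true(classify_sites(base_site(QD = 2.0))$pass)

  # FS = 100 fails a SNP but passes an indel (bound 200)
  snp <- classify_sites(base_site(FS = 100))
  indel <- classify_sites(base_site(FS = 100, ref = "ATG", alt = "A"))
  expect_equal(failed_set(snp), "FS")
  expect_true(indel$pass)

  # SI = 0.7 passes a SNP (bound 0.6) but fails an indel (bound 0.9)
  expect_true(classify_sites(base_site(SI = 0.7))$pass)
  expect_equal(failed_set(classify_sites(base_site(SI = 0.7, ref = "ATG",
                                                   alt = "A"))), "SI_low")

  # shared bounds
  expect_equal(failed_set(classify_sites(base_site(DP = 120000))), "DP")
  expect_equal(failed_set(classify_sites(base_site(AN = 4000))), "AN")
  expect_equal(failed_set(classify_sites(base_site(HW = 1e-8))), "HW")
  expect_equal(failed_set(classify_sites(base_site(SI = 1.5))), "SI_high")

  expect_error(classify_sites(base_site(type = "sv")), "unknown variant type")
})

test_that("a missing annotation cannot fail its rule", {
  s <- base_site(QD = NA_real_, MQ = NA_real_)
  expect_true(classify_sites(s)$pass)
  s2 <- base_site()
  s2$QD <- NULL
  expect_true(classify_sites(s2)$pass)
})

test_that("the failed-rule set is invariant under rule reordering", {
  s <- base_site(QD = 1.0, FS = 300, SI = 0.1)
  rules <- filter_rules()
  withr::with_seed(5, {
    for (i in 1:5) {
      shuffled <- rules[sample(nrow(rules)), ]
      expect_setequal(failed_set(classify_sites(s, rules = shuffled)),
                      c("QD", "FS", "SI_low"))
    }
  })
})

test_that("AN counts two chromosomes per called diploid genotype", {
  genos <- c(0, 1, 2, 1, NA, 0)
  expect_equal(allele_number(genos), 10L)
  # a fully called cohort of n individuals passes the AN bound iff 2n >= 4200
  expect_true(classify_sites(base_site(AN = allele_number(rep(1, 2101))))$pass)
  expect_equal(failed_set(classify_sites(
    base_site(AN = allele_number(rep(1, 2099))))), "AN")
})

test_that("the exact Hardy-Weinberg test matches hand enumeration", {
  # monomorphic: only one configuration exists
  expect_equal(hardy_weinberg_p(7, 0, 0), 1)
  expect_equal(hardy_weinberg_p(0, 0, 5), 1)

  # 2 A and 2 a alleles in 2 individuals: P(2 hets) = 2/3, P(0 hets) = 1/3
  # (placement enumeration: 6 ways to seat 2 A alleles in 4 slots)
  expect_equal(hardy_weinberg_p(0, 2, 0), 1)        # both outcomes <= 2/3
  expect_equal(hardy_weinberg_p(1, 0, 1), 1 / 3)

  # allele relabelling symmetry
  withr::with_seed(9, {
    for (i in 1:20) {
      cfg <- as.integer(rmultinom(1, sample(2:15, 1), rep(1 / 3, 3)))
      expect_equal(hardy_weinberg_p(cfg[1], cfg[2], cfg[3]),
                   hardy_weinberg_p(cfg[3], cfg[2], cfg[1]))
    }
  })
})

test_that("the exact test agrees with the pairing dynamic program", {
  withr::with_seed(21, {
    for (i in 1:30) {
      n <- sample(1:12, 1)
      cfg <- as.integer(rmultinom(1, n, c(0.3, 0.4, 0.3)))
      expect_equal(hardy_weinberg_p(cfg[1], cfg[2], cfg[3]),
                   hw_oracle_p(cfg[1], cfg[2], cfg[3]), tolerance = 1e-10)
    }
  })
})

test_that("homopolymer runs are found at the length threshold", {
  hp <- find_homopolymers("GGAAAAAAGG")
  expect_equal(length(hp), 1)
  expect_equal(GenomicRanges::start(hp), 3)
  expect_equal(GenomicRanges::end(hp), 8)

  expect_equal(length(find_homopolymers("GGAAAAAGG")), 0)  # run of 5
  expect_equal(length(find_homopolymers("NNNNNNNN")), 0)   # N never reported

  # regex oracle on random sequences
  withr::with_seed(31, {
    for (i in 1:10) {
      s <- paste(sample(c("A", "C", "G", "T", "N"), 300, replace = TRUE,
                        prob = c(0.3, 0.1, 0.3, 0.2, 0.1)), collapse = "")
      hits <- gregexpr("A{6,}|C{6,}|G{6,}|T{6,}", s)[[1]]
      found <- find_homopolymers(s)
      if (hits[1] == -1) {
        expect_equal(length(found), 0)
      } else {
        expect_equal(GenomicRanges::start(found), as.integer(hits))
        expect_equal(GenomicRanges::width(found),
                     attr(hits, "match.length"))
      }
    }
  })
})

test_that("repeat-mask building merges and unions like a per-base bitmap", {
  gr <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
  # disjoint inputs concatenate
  m <- build_repeat_mask(gr(10, 20), gr(100, 120))
  expect_equal(length(m), 2)
  # nested intervals collapse to the outer one
  m <- build_repeat_mask(gr(c(10, 12), c(50, 20)), gr(15, 18))
  expect_equal(GenomicRanges::start(m), 10)
  expect_equal(GenomicRanges::end(m), 50)
  # coverage equals the per-base union on random toy inputs
  withr::with_seed(13, {
    for (i in 1:5) {
      a <- sort(sample(9000, 8)); b <- sort(sample(9000, 6))
      trf <- gr(a[seq(1, 8, 2)], a[seq(1, 8, 2)] + sample(500, 4))
      hp <- gr(b[seq(1, 6, 2)], b[seq(1, 6, 2)] + sample(200, 3))
      m <- build_repeat_mask(trf, hp)
      expect_equal(sum(GenomicRanges::width(m)),
                   bitmap_coverage(c(trf, hp)))
    }
  })
  # chromosome naming mismatch across inputs is an error
  expect_error(build_repeat_mask(
    gr(1, 5), GenomicRanges::GRanges("1", IRanges::IRanges(1, 5))),
    "chromosome")
})

test_that("repeat masking tests the whole reference span of a variant", {
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1995, 2005))
  # SNP inside, SNP outside, deletion reaching into the mask from the left
  s <- tibble::tibble(
    chrom = "chr1", pos = c(2000L, 1990L, 1993L),
    ref = c("A", "A", "AAAA"), alt = c("G", "G", "A"),
    QD = 10
  )
  cl <- classify_sites(s, repeat_mask = mask)
  expect_equal(cl$masked_repeat, c(TRUE, FALSE, TRUE))
  expect_equal(cl$pass, c(FALSE, TRUE, FALSE))
  tally <- filter_tally(cl)
  expect_equal(tally$n_failed[tally$rule == "repeat_mask"], 2L)
})
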