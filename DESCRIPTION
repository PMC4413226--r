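Package: haplorefine
Title: Haplotype-Sharing Genotype Refinement for Sequenced Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines sequencing-based genotype calls in chip-typed, long-range
    phased cohorts by combining per-individual genotype likelihoods with
    haplotype-copying posteriors from a Li-and-Stephens style hidden Markov
    model over a phased scaffold. Includes hard site-quality filtering with
    simple-repeat masking, ancestral-state polarization of SNPs and indels
    against primate ancestor sequences, consequence-impact classification with
    transition/transversion summaries, imputation-accuracy metrics, and a
    deterministic cohort simulator so the whole pipeline runs end-to-end on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
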