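ANNOTATION_KEYS <- c("QD", "MQ", "FS", "HaplotypeScore", "MQRankSum",
                     "ReadPosRankSum", "DP", "AN", "HW", "SI")

#' Read a biallelic VCF into a site table
#'
#' Parses the fixed columns, the numeric annotation fields used by the site
#' filters (QD, MQ, FS, HaplotypeScore, MQRankSum, ReadPosRankSum, DP, AN,
#' HW, SI), AF, the ancestral-allele field AA, VEP-style CSQ consequence
#' terms, and per-sample genotype likelihoods. Phred-scaled PL triples are
#' converted to the linear scale (10^(-PL/10)), GL triples from log10;
#' triples are renormalised to sum to one (likelihoods are scale-invariant),
#' and a missing genotype field yields the uninformative triple. The
#' refinement posterior field PP round-trips when present.
#'
#' Multi-allelic records and indels longer than 60 bp are outside the
#' refinement model; they are skipped with one summary warning each.
#'
#' @param path Path to a VCF 4.x file (plain or gzipped).
#' @return Tibble with one row per retained record: fixed columns, `type`,
#'   `indel_length`, annotation columns, `consequences` (list), `gl` (list of
#'   individuals x 3 likelihood matrices) and `pp` (list of individuals x 4
#'   posterior matrices, or `NULL` entries). The sample names are in
#'   `attr(, "samples")`; skip counts in `attr(, "skipped")`.
#' @export
read_vcf <- function(path) {
  check_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  alt <- fix$ALT
  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  ilen <- abs(nchar(fix$REF) - nchar(ifelse(multi, fix$REF, alt)))
  too_long <- !multi & ilen > 60
  if (any(multi)) {
    rlang::warn(sprintf("skipped %d multi-allelic record(s)", sum(multi)))
  }
  if (any(too_long)) {
    rlang::warn(sprintf("skipped %d indel(s) longer than 60 bp", sum(too_long)))
  }
  keep <- !multi & !too_long

  sites <- tibble::tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    id = fix$ID[keep],
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    qual = suppressWarnings(as.numeric(fix$QUAL[keep])),
    filter = fix$FILTER[keep]
  )
  sites$type <- variant_type(sites$ref, sites$alt)
  sites$indel_length <- ifelse(sites$type == "indel",
                               abs(nchar(sites$ref) - nchar(sites$alt)), 0L)
  for (key in c(ANNOTATION_KEYS, "AF")) {
    val <- vcfR::extract.info(v, element = key, as.numeric = TRUE)
    sites[[key]] <- if (is.null(val)) NA_real_ else suppressWarnings(val[keep])
  }
  aa <- vcfR::extract.info(v, element = "AA")
  sites$AA <- if (is.null(aa)) NA_character_ else aa[keep]
  sites$consequences <- parse_csq(v, keep)

  samples <- character(0)
  gl <- rep(list(NULL), nrow(sites))
  pp <- rep(list(NULL), nrow(sites))
  if (ncol(v@gt) > 1) {
    samples <- colnames(v@gt)[-1]
    n_s <- length(samples)
    pl <- vcfR::extract.gt(v, element = "PL")
    glf <- vcfR::extract.gt(v, element = "GL")
    ppf <- vcfR::extract.gt(v, element = "PP")
    rows <- which(keep)
    for (j in seq_along(rows)) {
      i <- rows[j]
      gl[[j]] <- parse_likelihood_row(
        if (!is.null(pl)) pl[i, ] else rep(NA_character_, n_s),
        if (!is.null(glf)) glf[i, ] else rep(NA_character_, n_s))
      if (!is.null(ppf) && any(!is.na(ppf[i, ]))) {
        pp[[j]] <- do.call(rbind, lapply(ppf[i, ], function(x) {
          if (is.na(x)) rep(NA_real_, 4) else as.numeric(strsplit(x, ",")[[1]])
        }))
        colnames(pp[[j]]) <- c("P00", "P01", "P10", "P11")
      }
    }
  }
  sites$gl <- gl
  sites$pp <- pp
  attr(sites, "samples") <- samples
  attr(sites, "skipped") <- c(multiallelic = sum(multi), long_indel = sum(too_long))
  sites
}

check_vcf_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  bad <- body[vapply(strsplit(lines[body], "\t"), length, 0L) < 8]
  if (length(bad) > 0) {
    rlang::abort(sprintf("malformed VCF line %d: fewer than 8 fields", bad[1]))
  }
  invisible(TRUE)
}

parse_csq <- function(v, keep) {
  csq <- tryCatch(vcfR::extract.info(v, element = "CSQ"),
                  error = function(e) NULL)
  n <- sum(keep)
  if (is.null(csq)) return(rep(list(character(0)), n))
  idx <- 1L
  meta <- grep("^##INFO=<ID=CSQ", v@meta, value = TRUE)
  if (length(meta) == 1 && grepl("Format: ", meta)) {
    fields <- strsplit(sub('.*Format: ([^">]+).*', "\\1", meta), "\\|")[[1]]
    if ("Consequence" %in% fields) idx <- match("Consequence", fields)
  }
  lapply(csq[keep], function(x) {
    if (is.na(x)) return(character(0))
    per_tx <- strsplit(x, ",", fixed = TRUE)[[1]]
    terms <- vapply(per_tx, function(tx) strsplit(tx, "|", fixed = TRUE)[[1]][idx], "")
    unique(unlist(strsplit(terms, "&", fixed = TRUE)))
  })
}

parse_likelihood_row <- function(pl_row, gl_row) {
  n <- length(pl_row)
  out <- matrix(1 / 3, n, 3, dimnames = list(names(pl_row), c("L0", "L1", "L2")))
  for (s in seq_len(n)) {
    if (!is.na(pl_row[s])) {
      vals <- suppressWarnings(as.numeric(strsplit(pl_row[s], ",")[[1]]))
      if (length(vals) == 3 && !anyNA(vals)) out[s, ] <- 10^(-vals / 10)
    } else if (!is.na(gl_row[s])) {
      vals <- suppressWarnings(as.numeric(strsplit(gl_row[s], ",")[[1]]))
      if (length(vals) == 3 && !anyNA(vals)) out[s, ] <- 10^vals
    }
  }
  out / rowSums(out)
}

#' Write refined genotypes to a VCF
#'
#' Emits one record per site with the filter verdict in FILTER (failed rule
#' names, `repeat_mask` when masked, `PASS` otherwise), the refined
#' allele-frequency estimate and information score in INFO (AF, SI), and per
#' individual the hard phased genotype (GT, pipe-separated when phased) and
#' the phased genotype posterior quadruple (PP = P00,P01,P10,P11, six
#' decimals). A site where no individual had any read data is written with
#' `./.` genotypes and SI 0. The output round-trips through [read_vcf()].
#'
#' @param sites Site tibble (as from [read_vcf()] or [classify_sites()]).
#' @param results List of [refine_variant()] results, one per site row.
#' @param path Output path.
#' @param samples Sample names; defaults to `attr(sites, "samples")` or
#'   `ind<i>`.
#' @return `path`, invisibly.
#' @export
write_refined_vcf <- function(sites, results, path, samples = NULL) {
  sites <- tibble::as_tibble(sites)
  if (nrow(sites) != length(results)) {
    rlang::abort("one refinement result is required per site record")
  }
  n_ind <- if (length(results) > 0) nrow(results[[1]]$posteriors) else 0
  if (is.null(samples)) samples <- attr(sites, "samples")
  if (is.null(samples) || length(samples) != n_ind) {
    samples <- paste0("ind", seq_len(n_ind))
  }
  rule_names <- unique(filter_rules()$name)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=haplorefine",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Refined alternative allele frequency\">",
    "##INFO=<ID=SI,Number=1,Type=Float,Description=\"Imputation information score\">",
    sprintf("##FILTER=<ID=%s,Description=\"Failed %s rule\">", rule_names, rule_names),
    "##FILTER=<ID=repeat_mask,Description=\"Within the simple-repeat mask\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    "##FORMAT=<ID=PP,Number=4,Type=Float,Description=\"Phased genotype posteriors P00,P01,P10,P11\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  recs <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    res <- results[[i]]
    filt <- "PASS"
    if ("failed_rules" %in% names(sites)) {
      parts <- character(0)
      if (!is.na(sites$failed_rules[i]) && sites$failed_rules[i] != "") {
        parts <- strsplit(sites$failed_rules[i], ";")[[1]]
      }
      if (isTRUE(sites$masked_repeat[i])) parts <- c(parts, "repeat_mask")
      if (length(parts) > 0) filt <- paste(parts, collapse = ";")
    }
    si <- if (res$all_missing) 0 else res$info
    info <- sprintf("AF=%.6f;SI=%.6f", res$frequency, si)
    p <- res$posteriors
    gts <- if (res$all_missing) rep("./.", n_ind) else p$gt
    fmt <- vapply(seq_len(n_ind), function(s) {
      sprintf("%s:%.6f,%.6f,%.6f,%.6f", gts[s],
              p$P00[s], p$P01[s], p$P10[s], p$P11[s])
    }, "")
    recs[i] <- paste(c(sites$chrom[i], sites$pos[i],
                       if (!is.null(sites$id) && !is.na(sites$id[i])) sites$id[i] else ".",
                       sites$ref[i], sites$alt[i], ".", filt, info, "GT:PP", fmt),
                     collapse = "\t")
  }
  writeLines(c(header, recs), path)
  invisible(path)
}
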