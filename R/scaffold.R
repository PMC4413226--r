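#' Phased scaffold haplotypes
#'
#' The scaffold is the long-range phased haplotype set over chip markers:
#' a biallelic 0/1 allele matrix with one row per haplotype and one column
#' per marker, two haplotypes per individual. It is the donor pool the
#' copying HMM draws from.
#'
#' @param alleles Integer/numeric matrix, haplotypes x markers, entries 0/1.
#'   Row names, if absent, are generated as `<individual>_1`/`_2`.
#' @param individuals Character vector, one entry per haplotype row, naming
#'   the individual each haplotype belongs to. Each individual must
#'   contribute exactly two haplotypes. Default pairs consecutive rows.
#' @param markers Optional tibble of marker metadata (`chrom`, `pos`, and
#'   optionally `ref`, `alt`).
#' @return An object of class `scaffold_haplotypes`.
#' @export
scaffold_haplotypes <- function(alleles, individuals = NULL, markers = NULL) {
  alleles <- as.matrix(alleles)
  if (!all(alleles %in% c(0, 1))) {
    rlang::abort("scaffold alleles must be 0/1")
  }
  storage.mode(alleles) <- "integer"
  H <- nrow(alleles)
  if (H %% 2 != 0) rlang::abort("haplotype count must be even (2 per individual)")
  if (is.null(individuals)) {
    individuals <- rep(paste0("ind", seq_len(H / 2)), each = 2)
  }
  if (length(individuals) != H) {
    rlang::abort("`individuals` must name one individual per haplotype row")
  }
  tab <- table(individuals)
  if (any(tab != 2)) {
    rlang::abort("every individual must contribute exactly 2 haplotypes")
  }
  if (is.null(rownames(alleles))) {
    rownames(alleles) <- paste0(individuals, "_",
                                stats::ave(seq_len(H), individuals, FUN = seq_along))
  }
  if (!is.null(markers)) {
    markers <- tibble::as_tibble(markers)
    if (nrow(markers) != ncol(alleles)) {
      rlang::abort("marker metadata rows must match allele matrix columns")
    }
  }
  structure(
    list(alleles = alleles, individuals = individuals, markers = markers),
    class = "scaffold_haplotypes"
  )
}

#' @export
print.scaffold_haplotypes <- function(x, ...) {
  cat(sprintf("<scaffold_haplotypes> %d haplotypes (%d individuals) x %d markers\n",
              nrow(x$alleles), nrow(x$alleles) / 2, ncol(x$alleles)))
  invisible(x)
}

#' @export
dim.scaffold_haplotypes <- function(x) dim(x$alleles)

# row indices of the two haplotypes of the individual owning haplotype h
hap_partner <- function(scaffold, h) {
  ind <- scaffold$individuals[h]
  which(scaffold$individuals == ind)
}

#' Tidy a scaffold into long format
#'
#' @param x A `scaffold_haplotypes` object.
#' @param ... Unused.
#' @return Tibble with columns `haplotype`, `individual`, `marker`, `allele`.
#' @method tidy scaffold_haplotypes
#' @export
tidy.scaffold_haplotypes <- function(x, ...) {
  H <- nrow(x$alleles); M <- ncol(x$alleles)
  tibble::tibble(
    haplotype = rep(rownames(x$alleles), times = M),
    individual = rep(x$individuals, times = M),
    marker = rep(seq_len(M), each = H),
    allele = as.vector(x$alleles)
  )
}
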