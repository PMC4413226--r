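#' Read an interval set from a BED file
#'
#' BED input is 0-based half-open; the returned `GRanges` uses the usual
#' 1-based closed R convention (the conversion is done by the importer).
#'
#' @param path Path to a BED file.
#' @return A `GRanges` object.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Combine tandem-repeat and homopolymer intervals into a repeat mask
#'
#' The mask is the union of the two interval sets with overlapping and
#' adjacent intervals merged. Variants whose reference span touches the
#' mask are ignored by the site filters.
#'
#' @param trf `GRanges` of simple tandem repeat intervals.
#' @param homopolymers `GRanges` of homopolymer run intervals.
#' @return Merged `GRanges` mask.
#' @export
build_repeat_mask <- function(trf, homopolymers) {
  stopifnot(methods::is(trf, "GRanges"), methods::is(homopolymers, "GRanges"))
  if (length(trf) > 0 && length(homopolymers) > 0) {
    shared <- intersect(as.character(GenomicRanges::seqnames(trf)),
                        as.character(GenomicRanges::seqnames(homopolymers)))
    if (length(shared) == 0) {
      rlang::abort("interval sets share no chromosome names; naming mismatch?")
    }
  }
  GenomicRanges::reduce(c(GenomicRanges::granges(trf),
                          GenomicRanges::granges(homopolymers)))
}

#' Find homopolymer runs in a sequence
#'
#' Maximal runs of a single base (A, C, G or T) of at least `min_len` bases.
#' Runs of N are never reported.
#'
#' @param sequence Character scalar over A/C/G/T/N (case-insensitive).
#' @param min_len Minimum run length (default 6).
#' @param chrom Chromosome name for the returned ranges.
#' @return `GRanges` of homopolymer runs (1-based closed coordinates).
#' @export
find_homopolymers <- function(sequence, min_len = 6, chrom = "chr1") {
  stopifnot(is.character(sequence), length(sequence) == 1, min_len >= 1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) == 0) {
    return(GenomicRanges::GRanges())
  }
  runs <- rle(chars)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$lengths >= min_len & runs$values %in% c("A", "C", "G", "T")
  ir <- IRanges::IRanges(starts[keep], ends[keep])
  GenomicRanges::GRanges(rep(chrom, length(ir)), ir)
}

# TRUE for each variant whose reference span POS..POS+nchar(ref)-1 overlaps
# the mask.
span_masked <- function(chrom, pos, ref, mask) {
  if (is.null(mask) || length(mask) == 0) return(rep(FALSE, length(pos)))
  spans <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(pos, pos + nchar(ref) - 1))
  IRanges::overlapsAny(spans, mask)
}
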