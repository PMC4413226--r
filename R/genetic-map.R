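#' Build a genetic map
#'
#' A genetic map links physical marker positions (base pairs, 1-based) to
#' cumulative genetic positions (centiMorgans). Recombination distances
#' between adjacent markers drive the transition probabilities of the
#' haplotype-copying HMM.
#'
#' @param df Data frame with columns `pos` (base pairs, 1-based) and `cM`
#'   (cumulative genetic position in centiMorgans).
#' @return A tibble of class `genetic_map` with columns `pos` and `cM`.
#' @examples
#' genetic_map(data.frame(pos = c(1000, 2000), cM = c(0, 0.1)))
#' @export
genetic_map <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("pos", "cM") %in% names(df))) {
    rlang::abort("genetic map needs columns `pos` and `cM`")
  }
  df <- tibble::as_tibble(df[, c("pos", "cM")])
  if (nrow(df) == 0) rlang::abort("genetic map is empty")
  if (anyNA(df$pos) || anyNA(df$cM)) rlang::abort("genetic map contains NA")
  if (any(df$pos <= 0)) rlang::abort("positions must be positive")
  if (is.unsorted(df$pos, strictly = TRUE)) {
    rlang::abort("marker positions must be strictly increasing")
  }
  if (any(diff(df$cM) < 0)) {
    rlang::abort("genetic positions must be non-decreasing")
  }
  class(df) <- c("genetic_map", class(df))
  df
}

#' Read a genetic map from a two-column tab-separated file
#'
#' @param path Path to a tab-separated file with columns position (bp) and
#'   cumulative centiMorgans, sorted by position. A header line is optional.
#' @return A [genetic_map()] tibble.
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^[0-9]", sub("\t.*", "", first))
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          col.names = c("pos", "cM"),
                          colClasses = c("numeric", "numeric"))
  genetic_map(df)
}

#' Recombination distances between adjacent markers, in Morgans
#'
#' @param map A [genetic_map()].
#' @return Numeric vector of length `nrow(map) - 1`; element `i` is the
#'   genetic distance in Morgans between markers `i` and `i + 1`.
#' @export
recomb_dist <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  diff(map$cM) / 100
}

# Genetic position (cM) at arbitrary physical positions, linear between
# markers, clamped to the map ends outside the span.
interp_cM <- function(map, pos) {
  if (nrow(map) == 1) return(rep(map$cM, length(pos)))
  stats::approx(map$pos, map$cM, xout = pos, rule = 2, ties = "ordered")$y
}
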