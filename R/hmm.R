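#' Parameters of the haplotype-copying HMM
#'
#' The model treats each proband haplotype as an imperfect mosaic copy of the
#' other haplotypes in the scaffold pool. `lambda` is the per-marker mismatch
#' penalty (emission probability of observing a disagreeing allele), `ne` the
#' effective number of haplotypes in the population, entering the
#' recombination rate as rho_i = 4 * ne * r_i, and `sparsify` the fraction of
#' the per-marker maximum below which copying posteriors are dropped from
#' storage.
#'
#' @param lambda Mismatch penalty, in (0, 0.5). Default `1e-7`.
#' @param ne Effective haplotype count, > 0. Default `7000`.
#' @param sparsify Sparsification threshold in `[0, 1)` relative to the
#'   per-marker maximum posterior. Default `1e-6`.
#' @return A list of class `hmm_params`.
#' @export
hmm_params <- function(lambda = 1e-7, ne = 7000, sparsify = 1e-6) {
  if (!(lambda > 0 && lambda < 0.5)) rlang::abort("lambda must be in (0, 0.5)")
  if (!(ne > 0)) rlang::abort("ne must be positive")
  if (!(sparsify >= 0 && sparsify < 1)) rlang::abort("sparsify must be in [0, 1)")
  structure(list(lambda = lambda, ne = ne, sparsify = sparsify),
            class = "hmm_params")
}

#' Emission probability of the copying HMM
#'
#' @param proband_allele,donor_allele Alleles in \{0, 1\} (vectorised).
#' @param lambda Mismatch penalty in (0, 0.5).
#' @return `1 - lambda` where the alleles match, `lambda` where they differ.
#' @export
emission_prob <- function(proband_allele, donor_allele, lambda) {
  stopifnot(all(proband_allele %in% c(0, 1)), all(donor_allele %in% c(0, 1)),
            lambda > 0, lambda < 0.5)
  ifelse(proband_allele == donor_allele, 1 - lambda, lambda)
}

#' One row of the copying HMM transition matrix
#'
#' With rho = 4 * ne * r for genetic distance r (Morgans) and N donors, the
#' chain stays on the current donor with probability
#' `exp(-rho/N) + (1 - exp(-rho/N)) / N` and switches to each specific other
#' donor with probability `(1 - exp(-rho/N)) / N`.
#'
#' @param r Genetic distance between the two markers, in Morgans (>= 0).
#' @param ne Effective haplotype count.
#' @param n_donors Number of donor haplotypes N.
#' @return Named list with elements `stay` and `switch`;
#'   `stay + (N - 1) * switch == 1`.
#' @export
transition_row <- function(r, ne, n_donors) {
  if (r < 0) rlang::abort("genetic distance must be non-negative")
  stopifnot(n_donors >= 1, ne > 0)
  rho <- 4 * ne * r
  e <- exp(-rho / n_donors)
  list(stay = e + (1 - e) / n_donors, switch = (1 - e) / n_donors)
}

#' Copying-state posteriors for one proband haplotype
#'
#' Runs the forward-backward algorithm for haplotype `h` against the donor
#' pool (all other scaffold haplotypes), giving at every scaffold marker the
#' posterior probability gamma that `h` copies each donor there, conditional
#' on all markers. The forward pass starts uniform over donors and both
#' passes are rescaled per marker; results are invariant to the rescaling.
#' Posteriors below `params$sparsify` times the per-marker maximum are
#' dropped (ties at the cutoff are retained).
#'
#' @param scaffold A [scaffold_haplotypes()] pool.
#' @param h Row index of the proband haplotype in the pool.
#' @param map A [genetic_map()] with one entry per scaffold marker.
#' @param params [hmm_params()].
#' @param exclude_self_individual If `TRUE`, the proband's other haplotype is
#'   also removed from the donor pool (default `FALSE`: only `h` itself is
#'   excluded).
#' @param keep_markers Optional integer vector of marker indices at which to
#'   store posteriors (default: all markers). The forward-backward pass
#'   always spans all markers.
#' @return An object of class `copying_posteriors`: sparse per-marker donor
#'   weights.
#' @export
copying_posteriors <- function(scaffold, h, map, params = hmm_params(),
                               exclude_self_individual = FALSE,
                               keep_markers = NULL) {
  stopifnot(inherits(scaffold, "scaffold_haplotypes"),
            inherits(map, "genetic_map"), inherits(params, "hmm_params"))
  A <- scaffold$alleles
  H <- nrow(A); M <- ncol(A)
  if (M != nrow(map)) rlang::abort("map and scaffold marker counts differ")
  if (!(h >= 1 && h <= H)) rlang::abort("proband haplotype out of range")
  drop <- if (exclude_self_individual) hap_partner(scaffold, h) else h
  donors <- setdiff(seq_len(H), drop)
  N <- length(donors)
  if (N == 0) rlang::abort("empty donor set")
  if (is.null(keep_markers)) keep_markers <- seq_len(M)

  # emission matrix: markers x donors
  lam <- params$lambda
  pro <- A[h, ]
  E <- t(ifelse(A[donors, , drop = FALSE] == rep(pro, each = N), 1 - lam, lam))

  r <- if (M > 1) recomb_dist(map) else numeric(0)
  ex <- exp(-4 * params$ne * r / N)  # stay factor e^{-rho_i/N} per interval

  # forward, rescaled to sum 1 at each marker
  alpha <- matrix(0, M, N)
  a <- E[1, ] / N
  alpha[1, ] <- a / sum(a)
  if (M > 1) {
    for (i in 2:M) {
      a <- alpha[i - 1, ]
      a <- E[i, ] * (ex[i - 1] * a + (1 - ex[i - 1]) / N)
      alpha[i, ] <- a / sum(a)
    }
  }
  # backward
  beta <- matrix(0, M, N)
  beta[M, ] <- 1 / N
  if (M > 1) {
    for (i in (M - 1):1) {
      bE <- E[i + 1, ] * beta[i + 1, ]
      b <- ex[i] * bE + (1 - ex[i]) / N * sum(bE)
      beta[i, ] <- b / sum(b)
    }
  }

  gamma_kept <- vector("list", length(keep_markers))
  names(gamma_kept) <- as.character(keep_markers)
  retained <- numeric(length(keep_markers))
  for (j in seq_along(keep_markers)) {
    i <- keep_markers[j]
    g <- alpha[i, ] * beta[i, ]
    g <- g / sum(g)
    keep <- g >= params$sparsify * max(g)
    gamma_kept[[j]] <- list(k = donors[keep], gamma = g[keep])
    retained[j] <- sum(g[keep])
  }

  structure(
    list(h = h, donors = donors, markers = keep_markers,
         pos = map$pos[keep_markers], gamma = gamma_kept,
         retained_mass = retained, params = params),
    class = "copying_posteriors"
  )
}

#' @export
print.copying_posteriors <- function(x, ...) {
  cat(sprintf(
    "<copying_posteriors> haplotype %d, %d markers, %d donors, mean stored mass %.6f\n",
    x$h, length(x$markers), length(x$donors), mean(x$retained_mass)))
  invisible(x)
}

#' Tidy copying posteriors into long format
#'
#' @param x A `copying_posteriors` object.
#' @param ... Unused.
#' @return Tibble with columns `marker`, `pos`, `donor`, `gamma`.
#' @method tidy copying_posteriors
#' @export
tidy.copying_posteriors <- function(x, ...) {
  purrr::map2_dfr(x$gamma, seq_along(x$gamma), function(g, j) {
    tibble::tibble(marker = x$markers[j], pos = x$pos[j],
                   donor = g$k, gamma = g$gamma)
  })
}

#' Donor weights at an arbitrary position
#'
#' Interpolates the stored copying posteriors linearly in genetic distance
#' between the two markers flanking `pos`; outside the stored span the
#' nearest marker's posteriors are used. Weights are renormalised to sum to
#' one over the retained donors.
#'
#' @param post A [copying_posteriors()] object.
#' @param pos Physical target position (bp).
#' @param map The [genetic_map()] used to build `post`.
#' @return List with integer vector `k` (donor indices) and numeric `w`
#'   (weights summing to 1).
#' @export
interpolate_gamma <- function(post, pos, map) {
  stopifnot(inherits(post, "copying_posteriors"))
  if (length(post$gamma) == 0) rlang::abort("empty posteriors")
  mpos <- post$pos
  sparse_norm <- function(g) {
    w <- g$gamma / sum(g$gamma)
    list(k = g$k, w = w)
  }
  if (pos <= mpos[1]) return(sparse_norm(post$gamma[[1]]))
  n <- length(mpos)
  if (pos >= mpos[n]) return(sparse_norm(post$gamma[[n]]))
  right <- which(mpos >= pos)[1]
  if (mpos[right] == pos) return(sparse_norm(post$gamma[[right]]))
  left <- right - 1
  cms <- interp_cM(map, c(mpos[left], pos, mpos[right]))
  d <- cms[3] - cms[1]
  wr <- if (d > 0) (cms[2] - cms[1]) / d else 0.5
  gl <- post$gamma[[left]]; gr <- post$gamma[[right]]
  k <- union(gl$k, gr$k)
  v <- numeric(length(k))
  v[match(gl$k, k)] <- v[match(gl$k, k)] + (1 - wr) * gl$gamma
  v[match(gr$k, k)] <- v[match(gr$k, k)] + wr * gr$gamma
  list(k = k, w = v / sum(v))
}
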