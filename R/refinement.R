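#' Initialise per-haplotype alternative-allele probabilities
#'
#' For an individual with genotype likelihoods (L0, L1, L2), both of the
#' individual's haplotypes start at
#' theta = (L2 + L1/2) / (L0 + L1 + L2),
#' the expected alternative-allele dosage per haplotype under the
#' likelihoods alone.
#'
#' @param gl Numeric matrix (individuals x 3) or data frame with columns
#'   `L0`, `L1`, `L2`; likelihoods are scale-invariant.
#' @return Numeric vector, one theta per individual.
#' @export
init_theta <- function(gl) {
  L <- as_gl_matrix(gl)
  s <- rowSums(L)
  if (any(s <= 0)) rlang::abort("all-zero likelihood triple")
  (L[, 3] + 0.5 * L[, 2]) / s
}

as_gl_matrix <- function(gl) {
  if (is.data.frame(gl)) gl <- as.matrix(gl[, c("L0", "L1", "L2")])
  gl <- as.matrix(gl)
  if (ncol(gl) != 3) rlang::abort("genotype likelihoods need 3 columns (L0, L1, L2)")
  if (any(gl < 0)) rlang::abort("likelihoods must be non-negative")
  unname(gl)
}

#' Haplotype-sharing prediction of the alternative-allele probability
#'
#' The prediction for haplotype h is the gamma-weighted average of the
#' current theta over its donors: tau_h = sum_l gamma_{h,l} theta_l.
#'
#' @param weights Sparse donor weights: list with integer `k` (donor
#'   haplotype indices) and numeric `w`, e.g. from [interpolate_gamma()].
#' @param theta Numeric vector of current per-haplotype theta (full pool
#'   indexing).
#' @param exclude Integer vector of haplotype indices to drop from the donor
#'   set before predicting (weights are renormalised after exclusion).
#' @return List with `tau` and `flagged` (`TRUE` when no donors remained and
#'   the population mean of theta was used as a fallback prior).
#' @export
predict_tau <- function(weights, theta, exclude = integer(0)) {
  keep <- !(weights$k %in% exclude)
  if (!any(keep)) {
    return(list(tau = mean(theta), flagged = TRUE))
  }
  w <- weights$w[keep]
  list(tau = sum(w * theta[weights$k[keep]]) / sum(w), flagged = FALSE)
}

#' One refinement update for an individual's haplotype pair
#'
#' Combines the haplotype-sharing predictions (tau_h, tau_k) for the
#' individual's two haplotypes with the sequencing genotype likelihoods into
#' phased genotype probabilities
#' P00 = (1-tau_h)(1-tau_k) L0, P10 = tau_h (1-tau_k) L1/2,
#' P01 = (1-tau_h) tau_k L1/2, P11 = tau_h tau_k L2,
#' normalised, and the updated theta pair
#' theta_h' = (P10 + P11)/sum, theta_k' = (P01 + P11)/sum.
#'
#' @param tau_h,tau_k Predictions in `[0, 1]` for the two haplotypes.
#' @param L Numeric length-3 likelihood triple (L0, L1, L2).
#' @param individual Label used in the error message when the combination is
#'   contradictory (all four products zero).
#' @return List with normalised `P` (named P00, P10, P01, P11), `theta_h`,
#'   `theta_k`.
#' @export
update_pair <- function(tau_h, tau_k, L, individual = NA) {
  stopifnot(tau_h >= 0, tau_h <= 1, tau_k >= 0, tau_k <= 1, length(L) == 3)
  P <- c(P00 = (1 - tau_h) * (1 - tau_k) * L[[1]],
         P10 = tau_h * (1 - tau_k) * 0.5 * L[[2]],
         P01 = (1 - tau_h) * tau_k * 0.5 * L[[2]],
         P11 = tau_h * tau_k * L[[3]])
  s <- sum(P)
  if (s == 0) {
    rlang::abort(sprintf(
      "contradictory likelihoods and predictions for individual %s", individual))
  }
  P <- P / s
  list(P = P, theta_h = unname(P["P10"] + P["P11"]),
       theta_k = unname(P["P01"] + P["P11"]))
}

#' Imputation information score
#'
#' IMPUTE-style measure of how much of the binomial genotype variance at a
#' site the posterior genotype distribution captures:
#' 1 - mean(posterior genotype variance) / (2 f (1 - f)). Clipped below at
#' zero; values above one occur when the observed dosage variance exceeds the
#' binomial expectation. Defined as 1 for monomorphic sites (f of 0 or 1).
#'
#' @param posteriors Matrix or data frame with columns `P00`, `P01`, `P10`,
#'   `P11` (rows are individuals, each summing to 1).
#' @param frequency Alternative-allele frequency in `[0, 1]`.
#' @return Information score (scalar).
#' @export
info_score <- function(posteriors, frequency) {
  P <- as.matrix(as.data.frame(posteriors)[, c("P00", "P01", "P10", "P11")])
  if (frequency <= 0 || frequency >= 1) return(1)
  e <- P[, "P01"] + P[, "P10"] + 2 * P[, "P11"]
  e2 <- P[, "P01"] + P[, "P10"] + 4 * P[, "P11"]
  v <- pmax(e2 - e^2, 0)
  max(0, 1 - mean(v) / (2 * frequency * (1 - frequency)))
}

#' Refine one variant's genotypes by iterative haplotype sharing
#'
#' Fuses per-individual sequencing genotype likelihoods with
#' haplotype-copying donor weights into phased genotype posteriors. Each
#' iteration predicts tau for every haplotype from the previous iteration's
#' theta (synchronous schedule, so results do not depend on individual
#' ordering) and then updates every individual's haplotype pair with
#' [update_pair()]. Iteration stops when the largest absolute change in
#' theta falls below `eps`.
#'
#' @param gl Genotype likelihoods, individuals x 3 (matrix or data frame with
#'   `L0`, `L1`, `L2`). Row i belongs to the individual carrying haplotypes
#'   2i-1 and 2i.
#' @param weights List of sparse donor weights (`k`, `w`), one per haplotype,
#'   e.g. [interpolate_gamma()] at the target position.
#' @param eps Convergence threshold on max |theta change|. Default `1e-7`.
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @param exclude_self_individual If `TRUE`, the proband's other haplotype is
#'   removed from its donor set before predicting tau.
#' @return An object of class `refined_variant` with converged theta, a
#'   posterior tibble (one row per individual: P00, P01, P10, P11, dosage,
#'   hard phased call `gt`), allele-frequency estimate, information score,
#'   iteration count and convergence flag.
#' @export
refine_variant <- function(gl, weights, eps = 1e-7, max_iter = 1000,
                           exclude_self_individual = FALSE) {
  L <- as_gl_matrix(gl)
  n <- nrow(L)
  H <- 2 * n
  if (length(weights) != H) {
    rlang::abort("need one donor-weight entry per haplotype (2 per individual)")
  }
  s <- rowSums(L)
  if (any(s <= 0)) rlang::abort("all-zero likelihood triple")
  L <- L / s
  missing_ind <- abs(L[, 1] - L[, 2]) < 1e-12 & abs(L[, 2] - L[, 3]) < 1e-12

  theta <- rep(init_theta(L), each = 2)
  hap_of <- function(i) c(2L * i - 1L, 2L * i)
  partner <- function(h) ifelse(h %% 2 == 1, h + 1L, h - 1L)

  P <- matrix(0, n, 4, dimnames = list(NULL, c("P00", "P10", "P01", "P11")))
  tau <- numeric(H)
  tau_flagged <- logical(H)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    for (h in seq_len(H)) {
      excl <- if (exclude_self_individual) partner(h) else integer(0)
      pr <- predict_tau(weights[[h]], theta, exclude = excl)
      tau[h] <- pr$tau
      tau_flagged[h] <- pr$flagged
    }
    theta_new <- theta
    for (i in seq_len(n)) {
      hk <- hap_of(i)
      up <- update_pair(tau[hk[1]], tau[hk[2]], L[i, ], individual = i)
      P[i, ] <- up$P[colnames(P)]
      theta_new[hk[1]] <- up$theta_h
      theta_new[hk[2]] <- up$theta_k
    }
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < eps) {
      converged <- TRUE
      break
    }
  }

  post <- tibble::tibble(
    individual = seq_len(n),
    P00 = P[, "P00"], P01 = P[, "P01"], P10 = P[, "P10"], P11 = P[, "P11"]
  )
  post$dosage <- post$P01 + post$P10 + 2 * post$P11
  post$gt <- hard_call(P, tau)
  freq <- mean(theta)
  structure(
    list(theta = theta, posteriors = post, frequency = freq,
         info = info_score(post, freq), iterations = iter,
         converged = converged, tau = tau, tau_flagged = tau_flagged,
         all_missing = all(missing_ind), missing = missing_ind),
    class = "refined_variant"
  )
}

# argmax phased call per individual; an exact P01/P10 tie at the maximum is
# emitted as an unphased het unless the donor-weight support (tau) breaks it.
hard_call <- function(P, tau) {
  n <- nrow(P)
  gts <- character(n)
  labels <- c(P00 = "0|0", P10 = "1|0", P01 = "0|1", P11 = "1|1")
  for (i in seq_len(n)) {
    p <- P[i, ]
    m <- max(p)
    top <- names(p)[p == m]
    if (all(c("P10", "P01") %in% top)) {
      th <- tau[2 * i - 1]; tk <- tau[2 * i]
      gts[i] <- if (th > tk) "1|0" else if (tk > th) "0|1" else "0/1"
    } else {
      gts[i] <- labels[[top[1]]]
    }
  }
  gts
}

#' Likelihood-only genotype posteriors and calls
#'
#' The no-sharing baseline: posteriors proportional to the likelihood triple
#' (flat genotype prior), dosage its expectation, call its argmax.
#'
#' @param gl Genotype likelihoods (individuals x 3).
#' @return Tibble with `individual`, `g0`, `g1`, `g2`, `dosage`, `call`.
#' @export
likelihood_only <- function(gl) {
  L <- as_gl_matrix(gl)
  L <- L / rowSums(L)
  tibble::tibble(
    individual = seq_len(nrow(L)),
    g0 = L[, 1], g1 = L[, 2], g2 = L[, 3],
    dosage = L[, 2] + 2 * L[, 3],
    call = max.col(L, ties.method = "first") - 1L
  )
}

#' @export
print.refined_variant <- function(x, ...) {
  cat(sprintf(
    "<refined_variant> %d individuals, freq %.4f, info %.3f, %d iteration%s%s\n",
    nrow(x$posteriors), x$frequency, x$info, x$iterations,
    if (x$iterations == 1) "" else "s",
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Tidy per-individual refinement results
#'
#' @param x A `refined_variant`.
#' @param ... Unused.
#' @return The posterior tibble, one row per individual, with the genotype
#'   posterior quadruple, posterior dosage and hard phased call.
#' @method tidy refined_variant
#' @export
tidy.refined_variant <- function(x, ...) x$posteriors

#' One-row summary of a refined variant
#'
#' @param x A `refined_variant`.
#' @param ... Unused.
#' @return Tibble with frequency, info score, iterations and convergence.
#' @method glance refined_variant
#' @export
glance.refined_variant <- function(x, ...) {
  tibble::tibble(frequency = x$frequency, info = x$info,
                 iterations = x$iterations, converged = x$converged)
}
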