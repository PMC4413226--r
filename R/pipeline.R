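#' Refine one variant across a cohort from scaffold haplotypes
#'
#' The full chain for a single target variant: computes copying posteriors
#' for every haplotype in the pool at the two scaffold markers flanking the
#' target position, interpolates donor weights at the target, and runs the
#' iterative refinement.
#'
#' @param scaffold [scaffold_haplotypes()] pool (2 haplotypes per sequenced
#'   individual).
#' @param map [genetic_map()] over the scaffold markers.
#' @param gl Genotype likelihoods, one row per individual (matrix or data
#'   frame with L0, L1, L2), in scaffold individual order.
#' @param position Target variant position (bp).
#' @param params [hmm_params()].
#' @param eps,max_iter,exclude_self_individual Passed to [refine_variant()].
#' @return A [refine_variant()] result.
#' @export
refine_site <- function(scaffold, map, gl, position, params = hmm_params(),
                        eps = 1e-7, max_iter = 1000,
                        exclude_self_individual = FALSE) {
  H <- nrow(scaffold$alleles)
  keep <- flanking_markers(map, position)
  weights <- vector("list", H)
  for (h in seq_len(H)) {
    post <- copying_posteriors(scaffold, h, map, params,
                               keep_markers = keep)
    weights[[h]] <- interpolate_gamma(post, position, map)
  }
  refine_variant(gl, weights, eps = eps, max_iter = max_iter,
                 exclude_self_individual = exclude_self_individual)
}

flanking_markers <- function(map, position) {
  M <- nrow(map)
  if (position <= map$pos[1]) return(1L)
  if (position >= map$pos[M]) return(M)
  right <- which(map$pos >= position)[1]
  if (map$pos[right] == position) return(right)
  c(right - 1L, right)
}

#' Run the simulate-refine-measure chain for one cohort
#'
#' Convenience wrapper used by validation: simulates a cohort, refines the
#' planted variant, and reports accuracy of the refined calls next to the
#' likelihood-only baseline.
#'
#' @param config [sim_config()].
#' @param params [hmm_params()].
#' @param exclude_self_individual Passed through to the refinement.
#' @return List with the cohort (`sim`), the `refined` result, and a one-row
#'   `summary` tibble: realised frequency, info score, refined and
#'   likelihood-only concordance and dosage r-squared.
#' @export
evaluate_refinement <- function(config, params = hmm_params(),
                                exclude_self_individual = FALSE) {
  sim <- simulate_cohort(config)
  refined <- refine_site(sim$scaffold, sim$map, sim$gl, sim$target$position,
                         params = params,
                         exclude_self_individual = exclude_self_individual)
  truth <- sim$target$genotypes
  post <- refined$posteriors
  refined_calls <- gt_to_genotype(post$gt)
  base <- likelihood_only(sim$gl)
  summary <- tibble::tibble(
    maf_realized = sim$target$maf_realized,
    info = refined$info,
    concordance_refined = call_concordance(refined_calls, truth),
    concordance_likelihood = call_concordance(base$call, truth),
    r2_refined = suppressWarnings(dosage_r2(post$dosage, truth)),
    r2_likelihood = suppressWarnings(dosage_r2(base$dosage, truth)),
    iterations = refined$iterations,
    converged = refined$converged
  )
  list(sim = sim, refined = refined, summary = summary)
}

#' Parameter-recovery study across seeds and depths
#'
#' For each seed, simulates one cohort, computes the copying posteriors and
#' target-position donor weights once, then refines the planted variant
#' under read data simulated at each requested depth, comparing the refined
#' calls and dosages against the truth and against the likelihood-only
#' baseline.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param depths Mean depths to evaluate (default `c(20, 2)`).
#' @param config Base [sim_config()]; its seed field is replaced per run.
#' @param params [hmm_params()].
#' @return Tibble with one row per seed x depth: realised MAF, info score,
#'   concordance and dosage r-squared for the refined and likelihood-only
#'   calls, iterations and convergence.
#' @export
parameter_recovery <- function(seeds, depths = c(20, 2),
                               config = sim_config(), params = hmm_params()) {
  out <- list()
  for (s in seeds) {
    cfg <- config
    cfg$seed <- s
    pool <- simulate_haplotype_pool(cfg)
    target <- plant_target_variant(pool)
    H <- nrow(pool$scaffold$alleles)
    keep <- flanking_markers(pool$map, target$position)
    weights <- vector("list", H)
    for (h in seq_len(H)) {
      post <- copying_posteriors(pool$scaffold, h, pool$map, params,
                                 keep_markers = keep)
      weights[[h]] <- interpolate_gamma(post, target$position, pool$map)
    }
    for (d in seq_along(depths)) {
      gl <- simulate_likelihoods(target$genotypes, depths[d], cfg$error_rate,
                                 seed = s + 7919L * d)
      refined <- refine_variant(gl, weights)
      base <- likelihood_only(gl)
      truth <- target$genotypes
      out[[length(out) + 1]] <- tibble::tibble(
        seed = s, depth = depths[d],
        maf_realized = target$maf_realized,
        info = refined$info,
        concordance_refined = call_concordance(gt_to_genotype(refined$posteriors$gt), truth),
        concordance_likelihood = call_concordance(base$call, truth),
        r2_refined = suppressWarnings(dosage_r2(refined$posteriors$dosage, truth)),
        r2_likelihood = suppressWarnings(dosage_r2(base$dosage, truth)),
        iterations = refined$iterations,
        converged = refined$converged
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Convert hard phased calls to unphased genotype dosages
#'
#' @param gt Character vector of calls such as `"0|1"`, `"1|1"`, `"0/1"`,
#'   `"./."`.
#' @return Integer genotypes (0/1/2), `NA` for missing.
#' @export
gt_to_genotype <- function(gt) {
  a <- substr(gt, 1, 1)
  b <- substr(gt, 3, 3)
  ifelse(a == "." | b == ".", NA_integer_,
         as.integer(a) + as.integer(b))
}
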