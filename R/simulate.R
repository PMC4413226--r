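#' Simulation configuration
#'
#' Defines a synthetic cohort with the structure the refinement model
#' assumes: a small set of founder haplotypes, a pool of mosaic copies of
#' them over evenly spaced scaffold markers, one target variant perfectly
#' tagged by founder lineage, and binomial sequencing-read likelihoods.
#'
#' @param n_individuals Diploid individuals (default 200).
#' @param n_markers Scaffold markers (default 100).
#' @param n_founders Founder haplotypes the pool is a mosaic of (default 20,
#'   so with the default cohort of 400 haplotypes a single founder lineage
#'   carries about 5% of the pool — the granularity needed to plant a
#'   variant at the default MAF).
#' @param switch_rate Mosaic switch rate per centiMorgan (default 0.1, i.e.
#'   mean segment length 10 cM).
#' @param marker_spacing Marker spacing in centiMorgans (default 0.05, so the
#'   default scaffold spans about 5 cM).
#' @param maf Target minor allele frequency of the planted variant.
#' @param depth Mean sequencing depth per individual (Poisson).
#' @param error_rate Per-read base error rate.
#' @param shared_structure If `FALSE`, haplotypes are drawn independently
#'   (no founder sharing): a misspecification mode in which haplotype
#'   sharing carries no information about the target variant.
#' @param seed Random seed; mandatory, every stochastic step derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 200, n_markers = 100, n_founders = 20,
                       switch_rate = 0.1, marker_spacing = 0.05, maf = 0.05,
                       depth = 20, error_rate = 0.01, shared_structure = TRUE,
                       seed = 1) {
  stopifnot(n_individuals >= 1, n_markers >= 1, n_founders >= 1,
            switch_rate > 0, marker_spacing > 0,
            maf >= 0, maf <= 0.5, depth > 0,
            error_rate > 0, error_rate < 0.5, !is.null(seed))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a mosaic scaffold haplotype pool
#'
#' Founder haplotypes get independent 0/1 alleles at every marker; each pool
#' haplotype is a founder mosaic whose segment lengths are exponential in
#' genetic distance (rate `switch_rate` per cM), the founder being redrawn
#' uniformly at each boundary. The truth labels record which founder every
#' haplotype copies at every marker.
#'
#' @param config A [sim_config()].
#' @return List with `scaffold` ([scaffold_haplotypes()]), `map`
#'   ([genetic_map()]), `founders` (founder x marker allele matrix),
#'   `copy_truth` (haplotype x marker founder index), `segments` (tibble of
#'   mosaic segments with `haplotype`, `start_cM`, `end_cM`, `founder`,
#'   `censored`) and `config`.
#' @export
simulate_haplotype_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  M <- config$n_markers
  H <- 2L * config$n_individuals
  FN <- config$n_founders
  cm <- (seq_len(M) - 1) * config$marker_spacing
  map <- genetic_map(data.frame(pos = 1 + round(cm * 1e6), cM = cm))
  span <- if (M > 1) cm[M] else 0

  withr::with_seed(config$seed, {
    founders <- matrix(stats::rbinom(FN * M, 1, 0.5), FN, M)
    if (!config$shared_structure) {
      alleles <- matrix(stats::rbinom(H * M, 1, 0.5), H, M)
      copy_truth <- matrix(0L, H, M)
      segments <- tibble::tibble(haplotype = integer(), start_cM = numeric(),
                                 end_cM = numeric(), founder = integer(),
                                 censored = logical())
    } else {
      copy_truth <- matrix(0L, H, M)
      seg_list <- vector("list", H)
      for (j in seq_len(H)) {
        starts <- 0
        founder <- sample.int(FN, 1)
        founders_seq <- founder
        at <- stats::rexp(1, config$switch_rate)
        while (at < span) {
          starts <- c(starts, at)
          founders_seq <- c(founders_seq, sample.int(FN, 1))
          at <- at + stats::rexp(1, config$switch_rate)
        }
        ends <- c(starts[-1], at)
        seg_list[[j]] <- tibble::tibble(
          haplotype = j, start_cM = starts, end_cM = ends,
          founder = founders_seq,
          censored = ends > span
        )
        idx <- findInterval(cm, starts)
        copy_truth[j, ] <- founders_seq[idx]
      }
      segments <- dplyr::bind_rows(seg_list)
      alleles <- matrix(0L, H, M)
      for (j in seq_len(H)) alleles[j, ] <- founders[cbind(copy_truth[j, ], seq_len(M))]
    }
  })

  list(scaffold = scaffold_haplotypes(alleles), map = map, founders = founders,
       copy_truth = copy_truth, segments = segments, config = config)
}

# founder copied by each haplotype at a genetic position (cM)
founder_at <- function(pool, cm) {
  H <- nrow(pool$copy_truth)
  vapply(seq_len(H), function(j) {
    seg <- pool$segments[pool$segments$haplotype == j, ]
    seg$founder[findInterval(cm, seg$start_cM)]
  }, integer(1))
}

#' Plant a target variant on founder lineages
#'
#' Assigns allele 1 to every haplotype copying one of a chosen set of
#' founder lineages at the target position, so the variant is perfectly
#' tagged by local haplotype background. Founders are chosen greedily to
#' bring the realised carrier count as close as possible to the requested
#' MAF; when the target is unreachable the closest achievable frequency is
#' used and reported via a message.
#'
#' @param pool Output of [simulate_haplotype_pool()].
#' @param maf Target minor allele frequency.
#' @param position Physical target position (bp); default: midpoint of the
#'   central marker interval.
#' @return List with `position`, `hap_alleles` (0/1 per haplotype),
#'   `genotypes` (0/1/2 per individual), `maf_target`, `maf_realized`.
#' @export
plant_target_variant <- function(pool, maf = pool$config$maf, position = NULL) {
  map <- pool$map
  M <- nrow(map)
  if (is.null(position)) {
    mid <- max(1, floor(M / 2))
    position <- if (M > 1) floor((map$pos[mid] + map$pos[mid + 1]) / 2) else map$pos[1]
  }
  H <- nrow(pool$scaffold$alleles)
  target <- round(maf * H)
  if (!pool$config$shared_structure) {
    carriers_idx <- withr::with_seed(pool$config$seed + 1L,
                                     sample.int(H, target))
    hap <- as.integer(seq_len(H) %in% carriers_idx)
  } else {
    cm <- interp_cM(map, position)
    fa <- founder_at(pool, cm)
    counts <- tabulate(fa, nbins = pool$config$n_founders)
    ord <- order(counts)  # smallest lineages first: finer frequency granularity
    chosen <- integer(0)
    achieved <- 0
    for (f in ord) {
      if (counts[f] == 0) next
      if (abs(achieved + counts[f] - target) < abs(achieved - target)) {
        chosen <- c(chosen, f)
        achieved <- achieved + counts[f]
      }
    }
    if (length(chosen) == 0 && target > 0) {
      present <- which(counts > 0)
      chosen <- present[which.min(abs(counts[present] - target))]
    }
    hap <- as.integer(fa %in% chosen)
  }
  realized <- mean(hap)
  if (round(realized * H) != target) {
    message(sprintf("requested MAF %.4f unreachable; realised %.4f", maf, realized))
  }
  geno <- hap[seq(1, H, by = 2)] + hap[seq(2, H, by = 2)]
  list(position = position, hap_alleles = hap, genotypes = geno,
       maf_target = maf, maf_realized = realized)
}

#' Simulate sequencing-read genotype likelihoods
#'
#' Read counts are Poisson with the configured mean depth; the
#' alternative-read count is binomial with success probability
#' `error_rate`, 1/2, or `1 - error_rate` for true genotypes 0, 1, 2. The
#' likelihood of each genotype is the binomial probability of the observed
#' alternative count under that genotype. Zero reads give a flat
#' (uninformative) triple.
#'
#' @param truth_genotypes Integer vector of true genotypes (0/1/2).
#' @param depth Mean depth.
#' @param error_rate Per-read error rate in (0, 0.5).
#' @param seed Random seed.
#' @return Tibble with `individual`, `reads`, `alt_reads`, `L0`, `L1`, `L2`.
#' @export
simulate_likelihoods <- function(truth_genotypes, depth, error_rate, seed) {
  stopifnot(all(truth_genotypes %in% 0:2), depth > 0,
            error_rate > 0, error_rate < 0.5)
  n <- length(truth_genotypes)
  p_alt <- c(error_rate, 0.5, 1 - error_rate)[truth_genotypes + 1]
  withr::with_seed(seed, {
    reads <- stats::rpois(n, depth)
    alt <- stats::rbinom(n, reads, p_alt)
  })
  tibble::tibble(
    individual = seq_len(n), reads = reads, alt_reads = alt,
    L0 = stats::dbinom(alt, reads, error_rate),
    L1 = stats::dbinom(alt, reads, 0.5),
    L2 = stats::dbinom(alt, reads, 1 - error_rate)
  )
}

#' Simulate a complete cohort for one target variant
#'
#' Chains [simulate_haplotype_pool()], [plant_target_variant()] and
#' [simulate_likelihoods()] under sub-seeds derived from the configuration
#' seed, so identical configurations give identical cohorts.
#'
#' @param config A [sim_config()].
#' @return List with `scaffold`, `map`, `target` (planted-variant truth),
#'   `gl` (likelihood tibble), `pool` and `config`.
#' @export
simulate_cohort <- function(config) {
  pool <- simulate_haplotype_pool(config)
  target <- plant_target_variant(pool)
  gl <- simulate_likelihoods(target$genotypes, config$depth,
                             config$error_rate, seed = config$seed + 2L)
  list(scaffold = pool$scaffold, map = pool$map, target = target, gl = gl,
       pool = pool, config = config)
}

#' Draw SNPs under a uniform mutation model
#'
#' Reference base uniform over A/C/G/T and alternative uniform over the
#' three other bases: 4 of the 12 ordered substitution types are
#' transitions, so the expected Ts/Tv ratio is 0.5. Used as a
#' logic-inversion guard on the transition classifier.
#'
#' @param n Number of SNPs.
#' @param seed Random seed.
#' @return Tibble with `ref` and `alt`.
#' @export
simulate_uniform_snps <- function(n, seed) {
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  })
  tibble::tibble(ref = ref, alt = unname(alt))
}
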