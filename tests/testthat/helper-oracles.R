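# Independent oracles used across the suite.

# Exhaustive-path oracle for the copying HMM: sums the joint probability of
# every donor path explicitly. Tractable for pools of <= 5 haplotypes and
# <= 6 markers.
hmm_path_oracle <- function(scaffold, h, map, params) {
  A <- scaffold$alleles
  H <- nrow(A); M <- ncol(A)
  donors <- setdiff(seq_len(H), h)
  N <- length(donors)
  lam <- params$lambda
  r <- if (M > 1) diff(map$cM) / 100 else numeric(0)
  ex <- exp(-4 * params$ne * r / N)
  stay <- ex + (1 - ex) / N
  sw <- (1 - ex) / N

  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), M)))
  gamma <- matrix(0, M, N)
  total <- 0
  for (p in seq_len(nrow(paths))) {
    z <- paths[p, ]
    pr <- 1 / N
    for (i in seq_len(M)) {
      d <- donors[z[i]]
      pr <- pr * (if (A[h, i] == A[d, i]) 1 - lam else lam)
      if (i > 1) pr <- pr * (if (z[i] == z[i - 1]) stay[i - 1] else sw[i - 1])
    }
    total <- total + pr
    for (i in seq_len(M)) gamma[i, z[i]] <- gamma[i, z[i]] + pr
  }
  gamma / total  # markers x donors, donor order = setdiff(1:H, h)
}

# dense gamma matrix (markers x donors) from a copying_posteriors object
dense_gamma <- function(post) {
  N <- length(post$donors)
  G <- matrix(0, length(post$markers), N)
  for (j in seq_along(post$gamma)) {
    g <- post$gamma[[j]]
    G[j, match(g$k, post$donors)] <- g$gamma
  }
  G
}

# a random tiny HMM instance (pool <= 5 haplotypes after excluding none)
random_hmm_instance <- function() {
  H <- sample(3:5, 1)       # scaffold_haplotypes needs an even count; pad below
  if (H %% 2 == 1) H <- H + 1
  M <- sample(2:6, 1)
  A <- matrix(rbinom(H * M, 1, 0.5), H, M)
  cm <- cumsum(c(0, runif(M - 1, 0.01, 2)))
  map <- genetic_map(data.frame(pos = 1 + round(cm * 1e6) + seq_len(M), cM = cm))
  params <- hmm_params(lambda = 10^runif(1, -7, -0.5), ne = 10^runif(1, 1, 4),
                       sparsify = 0)
  list(scaffold = scaffold_haplotypes(A), map = map, params = params,
       h = sample(seq_len(H), 1))
}

# Exact distribution of the heterozygote count given allele counts, by a
# sequential-pairing dynamic program: individuals draw ordered pairs of
# alleles without replacement (hypergeometric steps). Independent of the
# closed-form multinomial used by the implementation.
hw_het_distribution <- function(nA, na) {
  n <- (nA + na) / 2
  stopifnot(n == round(n))
  # state: probability indexed by (remaining A alleles, hets so far)
  probs <- matrix(0, nA + 1, n + 1)
  probs[nA + 1, 1] <- 1
  remaining_total <- nA + na
  for (ind in seq_len(n)) {
    nxt <- matrix(0, nA + 1, n + 1)
    tot <- remaining_total - 2 * (ind - 1)
    for (a in 0:nA) {
      for (het in 0:(ind - 1)) {
        p <- probs[a + 1, het + 1]
        if (p == 0) next
        b <- tot - a  # remaining minor alleles
        denom <- tot * (tot - 1) / 2
        if (a >= 2) nxt[a - 1, het + 1] <- nxt[a - 1, het + 1] + p * (a * (a - 1) / 2) / denom
        if (a >= 1 && b >= 1) nxt[a, het + 2] <- nxt[a, het + 2] + p * (a * b) / denom
        if (b >= 2) nxt[a + 1, het + 1] <- nxt[a + 1, het + 1] + p * (b * (b - 1) / 2) / denom
      }
    }
    probs <- nxt
  }
  # collapse over remaining-A (must be a point mass at 0)
  dist <- colSums(probs)
  names(dist) <- 0:n
  dist[dist > 0]
}

# two-sided exact p-value from the DP distribution
hw_oracle_p <- function(n_AA, n_Aa, n_aa) {
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  dist <- hw_het_distribution(nA, na)
  obs <- dist[as.character(n_Aa)]
  sum(dist[dist <= obs * (1 + 1e-9)])
}

# per-base bitmap coverage of a set of intervals on a toy chromosome
bitmap_coverage <- function(gr, chrom_len = 10000) {
  covered <- logical(chrom_len)
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  for (i in seq_along(gr)) covered[st[i]:en[i]] <- TRUE
  sum(covered)
}

# build a small scaffold from a list of per-haplotype allele vectors
toy_scaffold <- function(...) {
  scaffold_haplotypes(do.call(rbind, list(...)))
}

# evenly spaced toy map over M markers
toy_map <- function(M, spacing_cM = 0.05) {
  cm <- (seq_len(M) - 1) * spacing_cM
  genetic_map(data.frame(pos = 1 + round(cm * 1e6), cM = cm))
}

# uniform donor weights over all haplotypes except h
uniform_weights <- function(H) {
  lapply(seq_len(H), function(h) {
    k <- setdiff(seq_len(H), h)
    list(k = k, w = rep(1 / length(k), length(k)))
  })
}
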