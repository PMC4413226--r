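test_that("theta initialisation follows the likelihood formula", {
  expect_equal(init_theta(rbind(c(1, 0, 0))), 0)
  expect_equal(init_theta(rbind(c(0, 0, 1))), 1)
  expect_equal(init_theta(rbind(c(1, 1, 1) / 3)), 0.5)
  expect_equal(init_theta(rbind(c(0.2, 0.6, 0.2))), 0.5)
  expect_error(init_theta(rbind(c(0, 0, 0))), "all-zero")
})

test_that("tau is the donor-weighted average of theta", {
  theta <- c(0, 0, 0.7, 1)
  expect_equal(predict_tau(list(k = c(1, 2), w = c(0.5, 0.5)), theta)$tau, 0)
  expect_equal(predict_tau(list(k = 3, w = 1), theta)$tau, 0.7)
  expect_equal(predict_tau(list(k = c(4, 1), w = c(0.25, 0.75)), theta)$tau,
               0.25)
  # exclusion renormalises the remaining donors
  pr <- predict_tau(list(k = c(3, 4), w = c(0.5, 0.5)), theta, exclude = 4)
  expect_equal(pr$tau, 0.7)
  expect_false(pr$flagged)
  # no donors left: fall back to the frequency prior, flagged
  pr <- predict_tau(list(k = 4, w = 1), theta, exclude = 4)
  expect_equal(pr$tau, mean(theta))
  expect_true(pr$flagged)
})

test_that("pair updates reproduce the worked phased-probability cases", {
  up <- update_pair(0, 0, c(0.9, 0.05, 0.05))
  expect_equal(unname(up$P["P00"]), 1)
  expect_equal(c(up$theta_h, up$theta_k), c(0, 0))

  up <- update_pair(1, 0, c(0, 1, 0))
  expect_equal(unname(up$P["P10"]), 1)
  expect_equal(c(up$theta_h, up$theta_k), c(1, 0))

  up <- update_pair(0.5, 0.5, c(0.25, 0.5, 0.25))
  expect_equal(unname(up$P), rep(0.25, 4))
  expect_equal(c(up$theta_h, up$theta_k), c(0.5, 0.5))

  expect_error(update_pair(0, 0, c(0, 1, 1), individual = "s7"), "s7")
})

test_that("delta-function homozygote likelihoods are a one-iteration fixed point", {
  gl <- rbind(c(1, 0, 0), c(0, 0, 1), c(1, 0, 0))
  res <- refine_variant(gl, uniform_weights(6))
  expect_true(res$converged)
  expect_equal(res$iterations, 1)
  expect_equal(res$posteriors$P00, c(1, 0, 1))
  expect_equal(res$posteriors$P11, c(0, 1, 0))
  expect_equal(res$posteriors$gt, c("0|0", "1|1", "0|0"))
  expect_equal(res$theta, c(0, 0, 1, 1, 0, 0))
})

test_that("uninformative data conserves the initial frequency", {
  gl <- matrix(1 / 3, 5, 3)
  res <- refine_variant(gl, uniform_weights(10))
  expect_equal(res$frequency, 0.5, tolerance = 1e-9)
  expect_true(res$all_missing)
  # posterior quadruples remain normalised
  sums <- rowSums(as.matrix(res$posteriors[, c("P00", "P01", "P10", "P11")]))
  expect_equal(sums, rep(1, 5), tolerance = 1e-9)
})

test_that("the information score spans no-information to full-information", {
  # delta posteriors at frequency-consistent genotypes
  P <- tibble::tibble(P00 = c(1, 1, 0), P01 = c(0, 0, 0),
                      P10 = c(0, 0, 1), P11 = c(0, 0, 0))
  f <- mean(c(0, 0, 1) / 2)
  expect_equal(info_score(P, f), 1)

  # Hardy-Weinberg prior posteriors carry no information
  f <- 0.3
  hw <- tibble::tibble(P00 = (1 - f)^2, P01 = f * (1 - f),
                       P10 = f * (1 - f), P11 = f^2)
  expect_equal(info_score(hw[rep(1, 10), ], f), 0)

  # monomorphic convention
  expect_equal(info_score(P, 0), 1)
  expect_equal(info_score(P, 1), 1)
})

test_that("an ambiguous 1-alt-of-8-reads het is rescued by haplotype sharing", {
  # scaffold backgrounds: A, B, C, D; individuals (A,B) (A,C) (C,D) (B,D)
  M <- 10
  bg <- list(
    A = rep(c(1, 0), 5),
    B = rep(c(0, 1), 5),
    C = rep(0, M),
    D = rep(1, M)
  )
  A <- rbind(bg$A, bg$B, bg$A, bg$C, bg$C, bg$D, bg$B, bg$D)
  sc <- scaffold_haplotypes(A)
  # chip-density genetic spacing relative to this tiny pool, so copying
  # states persist across the window (rho_i / N well below 1)
  map <- toy_map(M, spacing_cM = 0.002)

  eps <- 0.01
  amb <- c(dbinom(1, 8, eps), dbinom(1, 8, 0.5), dbinom(1, 8, 1 - eps))
  expect_equal(which.max(amb), 1)  # likelihood-only call is hom-ref
  gl <- rbind(amb,
              c(0, 1, 0),    # confident het sharing background A
              c(1, 0, 0),    # confident hom-ref (C, D)
              c(1, 0, 0))    # confident hom-ref (B, D)

  res <- refine_site(sc, map, gl, position = map$pos[5] + 10)
  post <- res$posteriors
  het_refined <- post$P01[1] + post$P10[1]
  het_likelihood_only <- amb[2] / sum(amb)
  expect_gt(het_refined, het_likelihood_only)
  expect_gt(het_refined, 0.5)
  expect_equal(gt_to_genotype(post$gt[1]), 1L)
  # the alternative allele lands on the shared background A
  expect_gt(post$P10[1], post$P01[1])
})

test_that("refinement beats likelihood-only calling on simulated cohorts", {
  rec <- suppressMessages(parameter_recovery(seeds = 1:2, depths = c(2)))
  expect_true(all(rec$converged))
  expect_true(all(rec$concordance_refined >= rec$concordance_likelihood))
  expect_true(all(rec$r2_refined > rec$r2_likelihood))
})

test_that("more read data never hurts an individual's posterior truth mass", {
  post_truth <- function(res, i, g) {
    p <- res$posteriors
    c(p$P00[i], p$P01[i] + p$P10[i], p$P11[i])[g + 1]
  }
  lows <- highs <- numeric(0)
  for (s in 1:5) {
    cfg <- sim_config(n_individuals = 40, n_markers = 50, seed = s)
    pool <- simulate_haplotype_pool(cfg)
    target <- suppressMessages(plant_target_variant(pool))
    keep <- haplorefine:::flanking_markers(pool$map, target$position)
    W <- lapply(seq_len(80), function(h) {
      interpolate_gamma(
        copying_posteriors(pool$scaffold, h, pool$map, keep_markers = keep),
        target$position, pool$map)
    })
    gl_lo <- simulate_likelihoods(target$genotypes, 2, 0.01, seed = s + 100)
    gl_hi <- gl_lo
    deeper <- simulate_likelihoods(target$genotypes, 8, 0.01, seed = s + 200)
    gl_hi[1, ] <- deeper[1, ]
    g1 <- target$genotypes[1]
    lows <- c(lows, post_truth(refine_variant(gl_lo, W), 1, g1))
    highs <- c(highs, post_truth(refine_variant(gl_hi, W), 1, g1))
  }
  expect_gte(mean(highs), mean(lows))
})

test_that("tidiers and summaries expose the refinement result", {
  gl <- rbind(c(1, 0, 0), c(0, 1, 0))
  res <- refine_variant(gl, uniform_weights(4))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("individual", "P00", "P01", "P10", "P11", "dosage", "gt"))
  gl1 <- glance(res)
  expect_equal(nrow(gl1), 1)
  expect_true(gl1$converged)
  expect_s3_class(autoplot(res), "ggplot")
})
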