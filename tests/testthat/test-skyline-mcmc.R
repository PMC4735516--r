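# Behavioural contracts of the Metropolis-Hastings sampler: determinism,
# thinning, sample counts, and prior recovery with the likelihood switched
# off. Full-scale statistical calibration lives in the acceptance suite.

small_aln <- function(seed = 1, n = 8, S = 40) {
  set.seed(seed)
  rand_alignment(n, S)
}

test_that("identical seeds give bit-identical retained samples", {
  aln <- small_aln()
  cfg <- mcmc_config(chain_length = 20000, thin = 20, seed = 99)
  p1 <- run_skyline_mcmc(aln, cfg)
  p2 <- run_skyline_mcmc(aln, cfg)
  expect_identical(p1$theta, p2$theta)
  expect_identical(p1$coal_times, p2$coal_times)
  expect_identical(p1$group_sizes, p2$group_sizes)
  expect_identical(p1$log_posterior, p2$log_posterior)
})

test_that("extending the chain preserves the seeded prefix of samples", {
  aln <- small_aln()
  cfg1 <- mcmc_config(chain_length = 10000, thin = 20,
                      burn_in_fraction = 0, seed = 5)
  cfg2 <- mcmc_config(chain_length = 30000, thin = 20,
                      burn_in_fraction = 0, seed = 5)
  p1 <- run_skyline_mcmc(aln, cfg1)
  p2 <- run_skyline_mcmc(aln, cfg2)
  k <- nrow(p1$theta)
  expect_identical(p1$theta, p2$theta[1:k, , drop = FALSE])
  expect_identical(p1$coal_times, p2$coal_times[1:k, , drop = FALSE])
})

test_that("retained sample count follows the burn-in/thinning contract", {
  aln <- small_aln()
  for (cl in c(20000, 50000)) {
    for (b in c(0, 0.1, 0.5)) {
      p <- run_skyline_mcmc(aln, mcmc_config(chain_length = cl, thin = 100,
                                             burn_in_fraction = b, seed = 2))
      expect_equal(nrow(p$theta), floor(cl * (1 - b) / 100))
    }
  }
})

test_that("chains too short for 100 retained samples are refused", {
  aln <- small_aln()
  expect_error(run_skyline_mcmc(aln, mcmc_config(chain_length = 1000,
                                                 thin = 100, seed = 1)),
               "too short")
})

test_that("the sampler needs at least 3 haplotypes and warns when invariant", {
  expect_error(run_skyline_mcmc(matrix("A", 2, 5),
                                mcmc_config(chain_length = 2e4, thin = 10)),
               "at least 3")
  expect_warning(run_skyline_mcmc(matrix("A", 4, 5),
                                  mcmc_config(chain_length = 2e4, thin = 10,
                                              seed = 1)),
                 "no variable sites")
})

test_that("group sizes stay a valid composition of n-1 along the chain", {
  aln <- small_aln(seed = 3, n = 12, S = 60)
  p <- run_skyline_mcmc(aln, mcmc_config(chain_length = 1e5, thin = 50,
                                         seed = 13))
  expect_true(all(rowSums(p$group_sizes) == 11L))
  expect_true(all(p$group_sizes >= 1L))
  expect_true(all(p$theta > 0))
  # coalescent times are sorted within each draw
  expect_true(all(apply(p$coal_times, 1, function(x) all(diff(x) >= 0))))
})

test_that("sampling with constant likelihood recovers the theta prior mean", {
  # independent log-uniform prior on [1e-6, 10]: mean (hi-lo)/log(hi/lo);
  # Monte-Carlo SE taken across independent replicate chains
  aln <- small_aln(seed = 8, n = 10, S = 30)
  target <- (10 - 1e-6) / log(10 / 1e-6)
  means <- vapply(1:4, function(s) {
    p <- run_skyline_mcmc(aln, mcmc_config(chain_length = 1e5, thin = 20,
                                           seed = 400 + s,
                                           sample_prior = TRUE,
                                           theta_prior = "independent"))
    mean(p$theta[, 1])
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - target), 3 * se + 0.05 * target)
})

test_that("posterior concentrates around theta truth on simulated data", {
  hm <- sim_haplotypes(20, 10000, 2.5e-8, 5000, seed = 271)
  aln <- block_alignment(hm)
  p <- run_skyline_mcmc(aln, mcmc_config(chain_length = 3e5, thin = 100,
                                         seed = 77),
                        invariant_sites = 5000 - ncol(aln))
  # grid-average Ne across draws should bracket the simulated Ne = 10,000
  dm <- blockskyline:::.skyline_draw_matrix(
    p, years_to_height(make_grid()$times, clock_scaling()))
  ne <- rowMeans(dm) / (2 * 2.5e-8)
  ci <- quantile(ne, c(0.025, 0.975))
  expect_lt(ci[1], 10000)
  expect_gt(ci[2], 10000)
})
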