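# JC69 pruning likelihood and the generalized-skyline coalescent density.

tree2 <- function(h) {
  genealogy_tree(parent = c(3L, 3L, NA), left = c(NA, NA, 1L),
                 right = c(NA, NA, 2L), height = c(0, 0, h), root = 3L,
                 n_tips = 2L)
}

test_that("identical sequences at vanishing height give S log(1/4)", {
  S <- 20L
  aln <- matrix("A", 2, S)
  expect_equal(tree_log_likelihood(aln, tree2(1e-12)), S * log(0.25),
               tolerance = 1e-8)
})

test_that("two tips at large height are independent: 2 S log(1/4)", {
  S <- 15L
  aln <- rbind(rep("A", S), rep("C", S))
  expect_equal(tree_log_likelihood(aln, tree2(1e4)), 2 * S * log(0.25),
               tolerance = 1e-8)
})

test_that("pruning equals brute-force state enumeration on small trees", {
  set.seed(301)
  for (r in 1:30) {
    n <- sample(3:4, 1)
    tree <- rand_genealogy(n)
    aln <- rand_alignment(n, 8)
    expect_equal(tree_log_likelihood(aln, tree),
                 brute_force_loglik(aln, tree), tolerance = 1e-10)
  }
})

test_that("invariant-site padding equals explicit monomorphic columns", {
  set.seed(302)
  tree <- rand_genealogy(4)
  aln <- rand_alignment(4, 6)
  padded <- cbind(aln, matrix("A", 4, 9))
  expect_equal(tree_log_likelihood(aln, tree, invariant_sites = 9),
               tree_log_likelihood(padded, tree), tolerance = 1e-10)
})

test_that("non-ACGT characters are rejected at alignment construction", {
  aln <- matrix(c("A", "N", "C", "G"), 2, 2)
  expect_error(tree_log_likelihood(aln, tree2(0.1)), "non-ACGT")
})

test_that("n=2 coalescent density has the exponential closed form", {
  th <- 0.37
  p <- skyline_params(1L, th)
  expect_equal(skyline_log_prior(tree2(th), p, theta_prior = "none"),
               -log(th) - 1, tolerance = 1e-12)
  t2 <- 0.05
  expect_equal(skyline_log_prior(tree2(t2), p, theta_prior = "none"),
               -log(th) - t2 / th, tolerance = 1e-12)
})

test_that("doubling theta rescales the n=2 coalescence density", {
  th <- 0.2; t <- 0.11
  f1 <- skyline_log_prior(tree2(t), skyline_params(1L, th),
                          theta_prior = "none")
  f2 <- skyline_log_prior(tree2(2 * t), skyline_params(1L, 2 * th),
                          theta_prior = "none")
  expect_equal(f2, f1 - log(2), tolerance = 1e-12)
})

test_that("n=4 density equals the hand per-interval product", {
  set.seed(303)
  for (r in 1:10) {
    tree <- rand_genealogy(4)
    gsz <- list(c(1L, 2L), c(2L, 1L), 3L, c(1L, 1L, 1L))[[sample(4, 1)]]
    th <- runif(length(gsz), 0.01, 1)
    p <- skyline_params(gsz, th)
    events <- tree$height[5:7]
    expect_equal(skyline_log_prior(tree, p, theta_prior = "none"),
                 hand_coalescent_logdensity(events, 4L, th, gsz),
                 tolerance = 1e-10)
  }
})

test_that("theta hyperpriors add the documented terms", {
  tree <- tree2(0.1)
  p <- skyline_params(1L, 0.5)
  base <- skyline_log_prior(tree, p, theta_prior = "none")
  expect_equal(skyline_log_prior(tree, p, theta_prior = "independent"),
               base - log(0.5), tolerance = 1e-12)
  # markov with one group reduces to the log-uniform term
  expect_equal(skyline_log_prior(tree, p, theta_prior = "markov"),
               base - log(0.5), tolerance = 1e-12)
  # out-of-bounds theta is excluded
  expect_equal(skyline_log_prior(tree, skyline_params(1L, 1e-8),
                                 theta_prior = "independent"), -Inf)
  # markov chain term for two groups: -log(th1) - log(th1) - th2/th1
  set.seed(304)
  tr4 <- rand_genealogy(4)
  th <- c(0.3, 0.08)
  p2 <- skyline_params(c(2L, 1L), th)
  expect_equal(skyline_log_prior(tr4, p2, theta_prior = "markov"),
               skyline_log_prior(tr4, p2, theta_prior = "none") -
                 log(th[1]) - log(th[1]) - th[2] / th[1],
               tolerance = 1e-12)
})

test_that("group sizes must sum to the number of coalescent events", {
  expect_error(skyline_log_prior(tree2(0.1), skyline_params(2L, 0.5)),
               "sum to")
})

test_that("skyline_at_time follows the piecewise lookup conventions", {
  draw <- list(thetas = c(1, 2, 3), coal_times = c(0.1, 0.2, 0.3, 0.5, 0.9),
               group_sizes = c(2L, 2L, 1L), root_height = 0.9)
  expect_equal(skyline_at_time(draw, 0), 1)          # tip-most group
  expect_equal(skyline_at_time(draw, 0.15), 1)
  expect_equal(skyline_at_time(draw, 0.2), 2)        # boundary -> older
  expect_equal(skyline_at_time(draw, 0.6), 3)
  expect_equal(skyline_at_time(draw, 5), 3)          # beyond root
  expect_equal(skyline_at_time(draw, c(0, 0.25, 2)), c(1, 2, 3))
  expect_error(skyline_at_time(draw, -0.1), "non-negative")
})

test_that("posterior_summary matches an independent recomputation", {
  theta <- rbind(c(1, 4), c(2, 6), c(3, 11))
  coal <- rbind(c(0.1, 0.3, 0.5), c(0.2, 0.4, 0.6), c(0.1, 0.2, 0.9))
  gsz <- matrix(rep(c(2L, 1L), each = 3), 3)
  post <- fake_posterior(theta, coal, gsz)
  times <- c(0, 0.35, 1)
  s <- posterior_summary(post, times)
  # direct per-draw evaluation
  direct <- t(sapply(1:3, function(k)
    skyline_at_time(posterior_draw(post, k), times)))
  expect_equal(s$skyline$mean, colMeans(direct))
  expect_equal(s$skyline$median, apply(direct, 2, median))
  expect_equal(s$skyline$sd, apply(direct, 2, sd))
  expect_equal(s$skyline$median[1], 2)   # draws {1,2,3} at t=0
  expect_equal(s$tmrca$median, median(coal[, 3]))
  # constant chain: zero SD everywhere
  post2 <- fake_posterior(theta[c(1, 1, 1), ], coal[c(1, 1, 1), ],
                          gsz[c(1, 1, 1), ])
  expect_true(all(posterior_summary(post2, times)$skyline$sd == 0))
  expect_error(posterior_summary(fake_posterior(theta[0, , drop = FALSE],
                                                coal[0, , drop = FALSE],
                                                gsz[0, , drop = FALSE]),
                                 times), "empty")
})
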