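# Weighted aggregation of block trajectories: closed-form minimizer,
# unweighted variant, weight handling, subset comparisons.

g6 <- make_grid(5000, 1000)

test_that("weights are inverse SDs with zero-SD flooring", {
  tr <- list(fake_trajectory(rep(10, 6), rep(2, 6), "a", g6),
             fake_trajectory(rep(20, 6), rep(4, 6), "b", g6))
  w <- compute_weights(tr)
  expect_equal(w[1, ], rep(0.5, 6))
  expect_equal(w[2, ], rep(0.25, 6))
  # zero SD floored at the smallest positive SD at that time point
  tr0 <- list(fake_trajectory(rep(10, 6), rep(0, 6), "a", g6),
              fake_trajectory(rep(20, 6), rep(4, 6), "b", g6))
  w0 <- compute_weights(tr0)
  expect_equal(w0[1, ], rep(0.25, 6))
  # all zero: equal weights with a warning
  trz <- list(fake_trajectory(rep(10, 6), rep(0, 6), "a", g6),
              fake_trajectory(rep(20, 6), rep(0, 6), "b", g6))
  expect_warning(wz <- compute_weights(trz), "equal weights")
  expect_true(all(wz == 1))
})

test_that("a single block aggregates to itself", {
  tr <- list(fake_trajectory(1:6 * 10, rep(1, 6), "a", g6))
  expect_equal(aggregate_trajectories(tr)$ne, 1:6 * 10)
})

test_that("equal weights give the arithmetic mean", {
  tr <- list(fake_trajectory(c(10, 20, 10, 20, 10, 20), rep(1, 6), "a", g6),
             fake_trajectory(c(30, 40, 30, 40, 30, 40), rep(1, 6), "b", g6))
  expect_equal(aggregate_trajectories(tr)$ne, c(20, 30, 20, 30, 20, 30))
  expect_equal(aggregate_unweighted(tr)$ne, c(20, 30, 20, 30, 20, 30))
  # aggregate with explicit equal weights == unweighted, exactly
  expect_identical(aggregate_trajectories(tr, weights = "equal")$ne,
                   aggregate_unweighted(tr)$ne)
  tr3 <- list(fake_trajectory(rep(100, 6), rep(1, 6), "a", g6),
              fake_trajectory(rep(200, 6), rep(1, 6), "b", g6),
              fake_trajectory(rep(300, 6), rep(1, 6), "c", g6))
  expect_equal(aggregate_unweighted(tr3)$ne, rep(200, 6))
})

test_that("closed form matches per-time numeric minimization", {
  set.seed(612)
  for (r in 1:10) {
    B <- 20; Tn <- 26
    g <- make_grid(25000, 1000)
    tr <- lapply(seq_len(B), function(j)
      fake_trajectory(runif(Tn, 1e3, 1e5), runif(Tn, 10, 1e4),
                      paste0("b", j), g))
    W <- compute_weights(tr)
    got <- aggregate_trajectories(tr, weights = W)$ne
    N <- t(vapply(tr, function(x) x$ne, numeric(Tn)))
    # the objective is convex and separable per time point: minimize each
    # coordinate by root-finding on the objective's derivative
    opt <- vapply(seq_len(Tn), function(i) {
      dobj <- function(x) sum(2 * W[, i]^2 * (x - N[, i]))
      uniroot(dobj, range(N[, i]), tol = 1e-10 * max(N[, i]))$root
    }, numeric(1))
    expect_equal(got, opt, tolerance = 1e-8)
  }
})

test_that("the aggregate is a convex combination and scale-invariant", {
  set.seed(613)
  g <- make_grid(25000, 1000)
  tr <- lapply(1:8, function(j)
    fake_trajectory(runif(26, 1e3, 1e5), runif(26, 10, 1e4),
                    paste0("b", j), g))
  W <- compute_weights(tr)
  x <- aggregate_trajectories(tr, weights = W)$ne
  N <- t(vapply(tr, function(t) t$ne, numeric(26)))
  expect_true(all(x >= apply(N, 2, min) - 1e-9))
  expect_true(all(x <= apply(N, 2, max) + 1e-9))
  # scaling all weights (or all SDs) leaves the minimizer unchanged
  expect_equal(aggregate_trajectories(tr, weights = 7 * W)$ne, x)
  tr2 <- lapply(tr, function(t) { t$sd <- 2 * t$sd; t })
  expect_equal(aggregate_trajectories(tr2)$ne, x)
})

test_that("weight_power 1 treats weights as already squared", {
  g <- make_grid(2000, 1000)
  tr <- list(fake_trajectory(c(10, 10, 10), c(1, 1, 1), "a", g),
             fake_trajectory(c(40, 40, 40), c(2, 2, 2), "b", g))
  W <- compute_weights(tr)              # 1 and 0.5
  p2 <- aggregate_trajectories(tr, weights = W, weight_power = 2)$ne
  p1 <- aggregate_trajectories(tr, weights = W, weight_power = 1)$ne
  expect_equal(p2, rep((1 * 10 + 0.25 * 40) / 1.25, 3))
  expect_equal(p1, rep((1 * 10 + 0.5 * 40) / 1.5, 3))
})

test_that("block order does not change the aggregate", {
  set.seed(614)
  tr <- lapply(1:5, function(j)
    fake_trajectory(runif(6, 1, 100), runif(6, 0.1, 10), paste0("b", j), g6))
  x <- aggregate_trajectories(tr)$ne
  expect_equal(aggregate_trajectories(rev(tr))$ne, x)
})

test_that("empty input is an error", {
  expect_error(aggregate_trajectories(list()), "no block trajectories")
})

test_that("subset comparison reports per-pair divergence", {
  tr <- lapply(1:6, function(j)
    fake_trajectory(rep(100, 6), rep(1, 6), paste0("b", j), g6))
  res <- subset_compare(tr, rep(c("x", "y"), 3))
  expect_equal(unname(res$max_relative_difference), 0)
  expect_named(res$trajectories, c("x", "y"))
  # single label: one trajectory, no comparison
  res1 <- subset_compare(tr, rep("only", 6))
  expect_null(res1$max_relative_difference)
  expect_length(res1$trajectories, 1L)
  expect_error(subset_compare(tr, c("x", "y")), "one label per block")
})

test_that("subset divergence shrinks with more blocks per subset", {
  set.seed(615)
  mk_set <- function(B) {
    tr <- lapply(seq_len(2 * B), function(j)
      fake_trajectory(1000 * exp(rnorm(6, 0, 0.5)), rep(1, 6),
                      paste0("b", j), g6))
    subset_compare(tr, rep(c("u", "v"), B))$max_relative_difference
  }
  small <- mean(replicate(20, mk_set(4)))
  large <- mean(replicate(20, mk_set(40)))
  expect_lt(large, small)
})
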