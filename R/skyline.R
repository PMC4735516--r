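# Bayesian skyline model for a single crossover-free block: a joint MCMC
# over the coalescent genealogy and grouped piecewise-constant population
# size parameters (thetas), with a JC69 substitution likelihood under a
# strict molecular clock. Time is measured in substitutions/site; theta is
# the pairwise-coalescence scale (rate k(k-1)/(2 theta) with k lineages) and
# converts to diploid Ne as theta / (2 mu) downstream.

.NT_CODES <- c(A = 0L, C = 1L, G = 2L, T = 3L)

# Collapse an alignment to unique site patterns with multiplicities.
# `invariant_sites` appends that many extra monomorphic columns (the
# non-segregating positions of a block, whose base identity is irrelevant
# under JC69) so that branch lengths stay on the per-bp scale.
.compress_alignment <- function(aln, invariant_sites = 0) {
  if (!is.matrix(aln) || !is.character(aln))
    stop("alignment must be a character matrix (haplotypes x sites)")
  if (invariant_sites < 0) stop("invariant_sites must be non-negative")
  aln <- toupper(aln)
  if (!all(aln %in% names(.NT_CODES)))
    stop("alignment contains non-ACGT characters")
  codes <- matrix(.NT_CODES[aln], nrow = nrow(aln))
  key <- apply(codes, 2L, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  patterns <- codes[, first, drop = FALSE]
  counts <- as.numeric(tab)
  if (invariant_sites > 0) {
    patterns <- cbind(patterns, 0L)
    counts <- c(counts, invariant_sites)
  }
  list(patterns = patterns, counts = counts,
       n_sites = ncol(aln) + invariant_sites)
}

#' Skyline parameters: grouped coalescent intervals and their thetas
#'
#' @param group_sizes Positive integers, one per group, summing to `n - 1`
#'   coalescent intervals (tip-most group first).
#' @param thetas Positive numeric, one theta (substitutions/site scale) per
#'   group.
#' @return Object of class `skyline_params`.
#' @export
skyline_params <- function(group_sizes, thetas) {
  group_sizes <- as.integer(group_sizes)
  if (length(group_sizes) != length(thetas))
    stop("one theta per group required")
  if (any(group_sizes < 1L)) stop("group sizes must be positive")
  if (any(thetas <= 0)) stop("thetas must be positive")
  structure(list(group_sizes = group_sizes, thetas = as.numeric(thetas)),
            class = "skyline_params")
}

.tree_to_c <- function(tree) {
  list(parent = ifelse(is.na(tree$parent), -1L, tree$parent - 1L),
       left = ifelse(is.na(tree$left), -1L, tree$left - 1L),
       right = ifelse(is.na(tree$right), -1L, tree$right - 1L),
       height = tree$height, root = tree$root - 1L)
}

#' JC69 log-likelihood of an alignment on a genealogy
#'
#' Felsenstein pruning under the Jukes-Cantor model with branch lengths
#' taken as node-height differences (heights in substitutions/site; the
#' strict clock is folded into the height units). Site patterns are
#' compressed before evaluation.
#'
#' @param alignment Character matrix of `A`/`C`/`G`/`T`, haplotypes in rows;
#'   row order must match tip indices 1..n of `tree`.
#' @param tree A [genealogy_tree()] with heights in substitutions/site.
#' @param invariant_sites Number of additional monomorphic sites to append
#'   (a block's non-segregating positions; keeps heights on the per-bp
#'   scale).
#' @return Log-likelihood (natural log).
#' @export
tree_log_likelihood <- function(alignment, tree, invariant_sites = 0) {
  cp <- .compress_alignment(alignment, invariant_sites)
  if (nrow(alignment) != tree$n_tips)
    stop("alignment rows must match the number of tips")
  tc <- .tree_to_c(tree)
  .jc69_loglik_cpp(cp$patterns, cp$counts, tc$left, tc$right, tc$height,
                   tc$root, tree$n_tips)
}

#' Generalized-skyline coalescent log density
#'
#' Iterates coalescent intervals from the tips to the root. An interval with
#' `k` lineages, duration `t` and governing theta contributes
#' `-k(k-1) t / (2 theta)`, plus `log(k(k-1) / (2 theta))` at the coalescent
#' event that closes it. A theta hyperprior can be added on top of the
#' coalescent density:
#'
#' * `"none"`: pure coalescent density (thetas only checked positive);
#' * `"independent"`: uniform on log theta within `theta_bounds`,
#'   independently per group;
#' * `"markov"`: the skyline's exponential smoothing prior — the tip-most
#'   group's theta is uniform on log within `theta_bounds` and each later
#'   group's theta is exponential with mean equal to its predecessor's,
#'   which shrinks groups containing little coalescent information towards
#'   their neighbours.
#'
#' @param tree A [genealogy_tree()].
#' @param params A [skyline_params()] with group sizes summing to
#'   `n_tips - 1`.
#' @param theta_prior Hyperprior on thetas (see above).
#' @param theta_bounds Support of the log-uniform component.
#' @return Log density; `-Inf` outside the prior's support.
#' @export
skyline_log_prior <- function(tree, params,
                              theta_prior = c("markov", "independent",
                                              "none"),
                              theta_bounds = c(1e-6, 10)) {
  theta_prior <- match.arg(theta_prior)
  if (sum(params$group_sizes) != tree$n_tips - 1L)
    stop("group sizes must sum to n_tips - 1")
  if (any(params$thetas <= 0)) return(-Inf)
  type <- match(theta_prior, c("none", "independent", "markov")) - 1L
  .skyline_logprior_cpp(tree$height, tree$n_tips, params$thetas,
                        params$group_sizes, theta_bounds[1L],
                        theta_bounds[2L], type)
}

#' MCMC configuration for the skyline sampler
#'
#' Desk-scale defaults (2e6 steps, thin 200, 10% burn-in) suit single-block
#' exploration; production analyses of many long blocks use far longer
#' chains (the schedule is fully configurable).
#'
#' @param chain_length Total Metropolis-Hastings steps.
#' @param thin Record every `thin`-th step after burn-in.
#' @param burn_in_fraction Fraction of the chain discarded (`0 <= b < 1`).
#' @param seed Integer seed; `NULL` leaves the R RNG untouched.
#' @param groups Number of skyline groups `m`; the default allocates about
#'   four coalescent intervals per group, capped at 10 groups
#'   (`max(1, min(10, (n - 1) %/% 4))`). Groups much smaller than that are
#'   dominated by the skew of their own posterior: with `k` intervals the
#'   per-group theta posterior is close to inverse-gamma with shape `k`,
#'   whose median sits `qgamma(0.5, k)`-fold off its scale — a +19% bias
#'   floor at `k = 2` that no chain length removes.
#' @param theta_prior `"markov"` (default; the skyline's exponential
#'   smoothing prior) or `"independent"` (log-uniform per group); see
#'   [skyline_log_prior()].
#' @param theta_bounds Support of the log-uniform component of the theta
#'   hyperprior (substitutions/site scale).
#' @param sample_prior If `TRUE` the substitution likelihood is replaced by
#'   a constant, so the chain samples the prior (validation mode).
#' @param move_weights Named numeric proposal weights for
#'   `theta_scale`, `joint_scale`, `node_slide`, `root_scale`,
#'   `narrow_exchange`, `group_move`, `group_scale` (the last scales one
#'   group's theta jointly with the interval durations it governs).
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(chain_length = 2e6, thin = 200,
                        burn_in_fraction = 0.1, seed = NULL, groups = NULL,
                        theta_prior = c("markov", "independent"),
                        theta_bounds = c(1e-6, 10), sample_prior = FALSE,
                        move_weights = c(theta_scale = 0.20,
                                         joint_scale = 0.10,
                                         node_slide = 0.25,
                                         root_scale = 0.10,
                                         narrow_exchange = 0.20,
                                         group_move = 0.05,
                                         group_scale = 0.10)) {
  theta_prior <- match.arg(theta_prior)
  if (chain_length < thin) stop("chain_length must be >= thin")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("burn_in_fraction must be in [0, 1)")
  if (theta_bounds[1L] <= 0 || theta_bounds[2L] <= theta_bounds[1L])
    stop("theta_bounds must be positive and increasing")
  structure(list(chain_length = chain_length, thin = as.integer(thin),
                 burn_in_fraction = burn_in_fraction, seed = seed,
                 groups = groups, theta_prior = theta_prior,
                 theta_bounds = theta_bounds,
                 sample_prior = isTRUE(sample_prior),
                 move_weights = move_weights),
            class = "mcmc_config")
}

.default_group_sizes <- function(n_intervals, m) {
  base <- n_intervals %/% m
  extra <- n_intervals %% m
  sizes <- rep(base, m)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

# Watterson's theta per site, halved to the pairwise-coalescence scale used
# by the skyline prior (theta = 2 Ne mu while Watterson estimates 4 Ne mu).
.watterson_init <- function(aln, invariant_sites = 0) {
  n <- nrow(aln)
  S <- sum(apply(aln, 2L, function(col) length(unique(col)) > 1L))
  if (S == 0L) return(1e-4)
  S / ((ncol(aln) + invariant_sites) * sum(1 / seq_len(n - 1L))) / 2
}

#' Run the Bayesian skyline MCMC on one block alignment
#'
#' Metropolis-Hastings over `(genealogy, thetas, group sizes)` with
#' proposals: per-group theta scaling, joint scaling of all heights and
#' thetas, uniform node-height slides, root-height scaling, narrow subtree
#' exchange, and moves of coalescent intervals between adjacent groups. The
#' chain starts from a UPGMA tree on p-distances with theta initialised at
#' half of Watterson's estimate. Runs are bit-reproducible given `seed`.
#'
#' @param alignment Character matrix (haplotypes x sites) of
#'   `A`/`C`/`G`/`T`, e.g. from [block_alignment()] or [read_block_fasta()];
#'   at least 3 haplotypes.
#' @param config An [mcmc_config()].
#' @param invariant_sites Number of monomorphic sites to append to the
#'   alignment (a SNP-only block alignment spanning `L` bp with `S` SNPs
#'   should pass `L - S` so branch lengths are substitutions per bp).
#' @return Object of class `skyline_posterior`: matrices of retained draws
#'   (`theta` K x m, `coal_times` K x (n-1) sorted ascending, `group_sizes`
#'   K x m), the joint `log_posterior` per draw, per-move acceptance rates,
#'   and the configuration.
#' @export
run_skyline_mcmc <- function(alignment, config = mcmc_config(),
                             invariant_sites = 0) {
  stopifnot(inherits(config, "mcmc_config"))
  n <- nrow(alignment)
  if (n < 3L) stop("need at least 3 haplotypes")
  cp <- .compress_alignment(alignment, invariant_sites)
  n_var <- sum(apply(alignment, 2L, function(col) length(unique(col)) > 1L))
  if (n_var == 0L)
    warning("no variable sites in alignment; posterior will be prior-driven")

  burn <- floor(config$chain_length * config$burn_in_fraction)
  n_retained <- floor(config$chain_length / config$thin) -
    floor(burn / config$thin)
  if (n_retained < 100L)
    stop("chain too short: fewer than 100 retained samples")

  m <- if (is.null(config$groups)) max(1L, min(10L, (n - 1L) %/% 4L)) else
    as.integer(config$groups)
  if (m < 1L || m > n - 1L) stop("groups must be in 1..n_tips-1")
  gsizes <- .default_group_sizes(n - 1L, m)

  tree <- .upgma_start_tree(alignment, invariant_sites)
  theta0 <- min(max(.watterson_init(alignment, invariant_sites),
                    config$theta_bounds[1L]),
                config$theta_bounds[2L])

  if (!is.null(config$seed)) set.seed(config$seed)
  tc <- .tree_to_c(tree)
  type <- match(config$theta_prior, c("none", "independent", "markov")) - 1L
  res <- .skyline_mcmc_cpp(cp$patterns, cp$counts,
                           tc$parent, tc$left, tc$right, tc$height, tc$root,
                           rep(theta0, m), gsizes,
                           config$theta_bounds[1L], config$theta_bounds[2L],
                           type, config$chain_length, config$thin,
                           config$burn_in_fraction, config$sample_prior,
                           unname(config$move_weights))
  move_names <- c("theta_scale", "joint_scale", "node_slide", "root_scale",
                  "narrow_exchange", "group_move", "group_scale")
  structure(list(theta = res$theta,
                 coal_times = res$coal_times,
                 group_sizes = res$group_sizes,
                 log_posterior = res$log_posterior,
                 n_tips = n, n_sites = cp$n_sites,
                 acceptance = setNames(as.numeric(res$acceptance), move_names),
                 config = config),
            class = "skyline_posterior")
}

#' @export
print.skyline_posterior <- function(x, ...) {
  cat(sprintf(
    "skyline_posterior: %d draws, %d tips, %d groups; median TMRCA %.4g subs/site\n",
    nrow(x$theta), x$n_tips, ncol(x$theta),
    median(x$coal_times[, ncol(x$coal_times)])))
  invisible(x)
}

#' Extract one posterior draw
#'
#' @param posterior A `skyline_posterior`.
#' @param k Draw index.
#' @return List with `thetas`, `coal_times` (sorted ascending),
#'   `group_sizes`, `root_height`.
#' @export
posterior_draw <- function(posterior, k) {
  list(thetas = posterior$theta[k, ],
       coal_times = posterior$coal_times[k, ],
       group_sizes = posterior$group_sizes[k, ],
       root_height = posterior$coal_times[k, ncol(posterior$coal_times)])
}

#' Evaluate one draw's piecewise-constant skyline at given times
#'
#' Group boundaries sit at the coalescent events closing each group; the
#' function is right-continuous in (backwards) time, so a time exactly at a
#' boundary takes the older interval's theta, and times beyond the draw's
#' root height return the root-most group's theta.
#'
#' @param draw A draw from [posterior_draw()].
#' @param t Non-negative time(s) in substitutions/site.
#' @return Theta value(s) at `t`.
#' @export
skyline_at_time <- function(draw, t) {
  if (any(t < 0)) stop("time must be non-negative")
  bounds <- draw$coal_times[cumsum(draw$group_sizes)]
  g <- pmin(findInterval(t, bounds) + 1L, length(draw$thetas))
  draw$thetas[g]
}

# K x length(times) matrix of theta draws evaluated on a time grid
.skyline_draw_matrix <- function(posterior, times) {
  K <- nrow(posterior$theta)
  out <- matrix(0, K, length(times))
  m <- ncol(posterior$theta)
  csum <- matrix(apply(posterior$group_sizes, 1L, cumsum),
                 nrow = K, byrow = TRUE)
  for (k in seq_len(K)) {
    bounds <- posterior$coal_times[k, csum[k, ]]
    g <- pmin(findInterval(times, bounds) + 1L, m)
    out[k, ] <- posterior$theta[k, g]
  }
  out
}

#' Summarize a skyline posterior on a time grid
#'
#' @param posterior A `skyline_posterior` with at least one retained draw.
#' @param times Non-negative times in substitutions/site.
#' @return List with `skyline`, a data.frame of per-time `mean`, `median`,
#'   `sd`, `lower95`, `upper95` across draws of [skyline_at_time()], and
#'   `tmrca`, the same statistics for the root height.
#' @export
posterior_summary <- function(posterior, times) {
  if (nrow(posterior$theta) == 0L) stop("empty posterior")
  if (any(times < 0)) stop("times must be non-negative")
  dm <- .skyline_draw_matrix(posterior, times)
  qs <- apply(dm, 2L, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  sky <- data.frame(time = times,
                    mean = colMeans(dm),
                    median = qs[2L, ],
                    sd = apply(dm, 2L, sd),
                    lower95 = qs[1L, ],
                    upper95 = qs[3L, ])
  rh <- posterior$coal_times[, ncol(posterior$coal_times)]
  tq <- quantile(rh, c(0.025, 0.5, 0.975), names = FALSE)
  list(skyline = sky,
       tmrca = list(mean = mean(rh), median = tq[2L], sd = sd(rh),
                    lower95 = tq[1L], upper95 = tq[3L]))
}
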