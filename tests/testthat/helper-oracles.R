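# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own computational paths.

# --- random fixtures --------------------------------------------------------

rand_hap_matrix <- function(n_hap, n_sites, p_alt = 0.4) {
  al <- matrix(rbinom(n_hap * n_sites, 1L, p_alt), n_hap, n_sites)
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1L))
  haplotype_matrix("chrT", seq_len(n_sites) * 10L, ref, unname(alt), al,
                   paste0("h", seq_len(n_hap)))
}

# random ultrametric genealogy via sequential random joins; heights on the
# substitutions/site scale
rand_genealogy <- function(n, max_height = 0.3) {
  tot <- 2L * n - 1L
  parent <- rep(NA_integer_, tot)
  left <- rep(NA_integer_, tot)
  right <- rep(NA_integer_, tot)
  height <- numeric(tot)
  active <- seq_len(n)
  h <- 0
  for (v in (n + 1L):tot) {
    pick <- sample(seq_along(active), 2L)
    h <- h + runif(1L, 0.05, 1) * max_height / n
    a <- active[pick[1L]]; b <- active[pick[2L]]
    left[v] <- a; right[v] <- b
    parent[a] <- v; parent[b] <- v
    height[v] <- h
    active <- c(active[-pick], v)
  }
  genealogy_tree(parent, left, right, height, root = tot, n_tips = n)
}

rand_alignment <- function(n, S) {
  matrix(sample(c("A", "C", "G", "T"), n * S, replace = TRUE), n, S)
}

# --- four-gamete partition oracle -------------------------------------------

# all-pairs compatibility of a contiguous window, straight from the
# definition
window_compatible <- function(hm, lo, hi) {
  if (lo == hi) return(TRUE)
  for (i in lo:(hi - 1L))
    for (j in (i + 1L):hi)
      if (length(unique(paste0(hm$alleles[, i], hm$alleles[, j]))) >= 4L)
        return(FALSE)
  TRUE
}

# brute-force partition: repeatedly take the longest left-anchored
# all-pairs-compatible window
brute_force_partition <- function(hm) {
  S <- ncol(hm$alleles)
  out <- list()
  lo <- 1L
  while (lo <= S) {
    hi <- lo
    while (hi < S && window_compatible(hm, lo, hi + 1L)) hi <- hi + 1L
    out[[length(out) + 1L]] <- c(lo, hi)
    lo <- hi + 1L
  }
  do.call(rbind, out)
}

# --- JC69 likelihood oracle -------------------------------------------------

jc69_p <- function(d) {
  e <- exp(-4 / 3 * d)
  function(x, y) if (x == y) 0.25 + 0.75 * e else 0.25 - 0.25 * e
}

# direct summation over all internal-state assignments (4^(n-1) terms)
brute_force_loglik <- function(aln, tree) {
  n <- tree$n_tips
  tot <- 2L * n - 1L
  internals <- (n + 1L):tot
  codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  obs <- matrix(codes[aln], nrow = n)
  states <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  edges <- which(!is.na(tree$parent))
  pfun <- lapply(edges, function(v)
    jc69_p(tree$height[tree$parent[v]] - tree$height[v]))
  ll <- 0
  for (s in seq_len(ncol(aln))) {
    tot_p <- 0
    for (r in seq_len(nrow(states))) {
      st <- numeric(tot)
      st[seq_len(n)] <- obs[, s]
      st[internals] <- states[r, ]
      p <- 0.25
      for (ei in seq_along(edges)) {
        v <- edges[ei]
        p <- p * pfun[[ei]](st[tree$parent[v]], st[v])
      }
      tot_p <- tot_p + p
    }
    ll <- ll + log(tot_p)
  }
  ll
}

# --- coalescent density oracle ----------------------------------------------

# per-interval product computed directly from sorted event times
hand_coalescent_logdensity <- function(event_times, n, thetas, group_sizes) {
  times <- sort(event_times)
  grp <- rep(seq_along(group_sizes), group_sizes)
  lp <- 0
  tprev <- 0
  k <- n
  for (e in seq_along(times)) {
    th <- thetas[grp[e]]
    d <- times[e] - tprev
    lp <- lp + log(k * (k - 1) / (2 * th)) - k * (k - 1) * d / (2 * th)
    tprev <- times[e]
    k <- k - 1L
  }
  lp
}

# --- misc -------------------------------------------------------------------

# batch-means Monte Carlo standard error for a (possibly autocorrelated)
# chain
batch_means_se <- function(x, n_batches = 40L) {
  bs <- floor(length(x) / n_batches)
  m <- vapply(seq_len(n_batches),
              function(b) mean(x[((b - 1L) * bs + 1L):(b * bs)]),
              numeric(1L))
  sd(m) / sqrt(n_batches)
}

# fabricate a skyline_posterior object from explicit draws
fake_posterior <- function(theta, coal_times, group_sizes) {
  structure(list(theta = theta, coal_times = coal_times,
                 group_sizes = group_sizes,
                 log_posterior = rep(0, nrow(theta)),
                 n_tips = ncol(coal_times) + 1L,
                 n_sites = 0L, acceptance = NULL, config = NULL),
            class = "skyline_posterior")
}

# fabricate a block_trajectory on a grid
fake_trajectory <- function(ne, sd, id = "b", grid = make_grid()) {
  structure(list(block_id = id, ne = ne, sd = sd,
                 tmrca_years = 1e6, grid = grid),
            class = "block_trajectory")
}
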