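# Seeded coalescent fixture generator: genealogies under piecewise-constant
# demography (diploid convention: k lineages coalesce at total rate
# k(k-1)/(4 Ne) per generation), infinite-sites binary mutations placed
# uniformly on a bp span, optional single-crossover splicing and clean
# two-deme splits. Every generator is deterministic given `seed` (which
# seeds R's RNG).

#' Piecewise-constant demographic model
#'
#' @param epochs `data.frame` with columns `start_gen` (epoch start,
#'   generations before present; first must be 0, strictly increasing) and
#'   `ne` (positive diploid Ne during the epoch, extending to the next
#'   start or infinity).
#' @return Object of class `demography_model`.
#' @export
demography_model <- function(epochs = data.frame(start_gen = 0, ne = 10000)) {
  if (!all(c("start_gen", "ne") %in% names(epochs)))
    stop("epochs needs columns start_gen and ne")
  if (epochs$start_gen[1L] != 0) stop("first epoch must start at generation 0")
  if (nrow(epochs) > 1L && any(diff(epochs$start_gen) <= 0))
    stop("epoch start times must be strictly increasing")
  if (any(epochs$ne <= 0)) stop("Ne must be positive")
  structure(list(epochs = epochs), class = "demography_model")
}

.const_demography <- function(ne) demography_model(data.frame(start_gen = 0, ne = ne))

# Coalesce a pool of lineages from time t0 (generations) under `demog`,
# stopping at t_stop (Inf = until one lineage remains). `nodes` are current
# node ids; returns updated state. Used by sim_tree and sim_two_demes.
.coalesce_pool <- function(state, nodes, t0, t_stop, demog) {
  starts <- demog$epochs$start_gen
  nes <- demog$epochs$ne
  t <- t0
  while (length(nodes) > 1L && t < t_stop) {
    k <- length(nodes)
    ep <- findInterval(t, starts)
    ne <- nes[ep]
    rate <- k * (k - 1) / (4 * ne)
    wait <- rexp(1L, rate)
    nxt <- if (ep < length(starts)) starts[ep + 1L] else Inf
    if (t + wait > min(nxt, t_stop)) {
      t <- min(nxt, t_stop)
      next
    }
    t <- t + wait
    pick <- sample.int(k, 2L)
    v <- state$next_node
    state$next_node <- v + 1L
    a <- nodes[pick[1L]]; b <- nodes[pick[2L]]
    state$left[v] <- a; state$right[v] <- b
    state$parent[a] <- v; state$parent[b] <- v
    state$height[v] <- t
    nodes <- c(nodes[-pick], v)
  }
  state$active <- nodes
  state$time <- t
  state
}

.new_tree_state <- function(n) {
  tot <- 2L * n - 1L
  list(parent = rep(NA_integer_, tot), left = rep(NA_integer_, tot),
       right = rep(NA_integer_, tot), height = numeric(tot),
       next_node = n + 1L, active = seq_len(n), time = 0)
}

.state_to_tree <- function(state, n, tip_labels = NULL) {
  genealogy_tree(state$parent, state$left, state$right, state$height,
                 root = 2L * n - 1L, n_tips = n, tip_labels = tip_labels,
                 units = "generations")
}

#' Simulate a coalescent genealogy
#'
#' Time-rescaled coalescent under a piecewise-constant demography: with
#' `k` lineages in an epoch of diploid size Ne, the waiting time to the
#' next coalescence is exponential with rate `k(k-1)/(4 Ne)` per
#' generation, truncated at epoch boundaries.
#'
#' @param n Number of tips (`>= 2`).
#' @param demography A [demography_model()], or a single Ne value.
#' @param seed Optional integer seed (sets the R RNG).
#' @return A [genealogy_tree()] with heights in generations.
#' @export
sim_tree <- function(n, demography, seed = NULL) {
  if (n < 2L) stop("need at least 2 tips")
  if (is.numeric(demography)) demography <- .const_demography(demography)
  stopifnot(inherits(demography, "demography_model"))
  if (!is.null(seed)) set.seed(seed)
  state <- .new_tree_state(n)
  state <- .coalesce_pool(state, seq_len(n), 0, Inf, demography)
  .state_to_tree(state, n)
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Mutations fall on branches as a Poisson process with rate `mu` per site
#' per generation over `span_bp` sites; each mutation creates a new
#' biallelic site at a uniformly drawn unique position in `1..span_bp`
#' (positions are resampled on collision), with the carriers being the
#' tips descending from the mutated branch. REF/ALT nucleotides are drawn
#' uniformly among distinct pairs.
#'
#' @param tree A [genealogy_tree()] with heights in generations.
#' @param mu Mutation rate per site per generation.
#' @param span_bp Number of base pairs the block spans.
#' @param seed Optional integer seed.
#' @param chromosome Chromosome name for the resulting matrix.
#' @return A [haplotype_matrix()]; zero mutations give a zero-site matrix
#'   (not an error), flagged by `n_sites(x) == 0`.
#' @export
sim_sequences <- function(tree, mu, span_bp, seed = NULL,
                          chromosome = "sim1") {
  stopifnot(inherits(tree, "genealogy_tree"))
  if (!is.null(seed)) set.seed(seed)
  n <- tree$n_tips
  tot <- 2L * n - 1L
  blen <- numeric(tot)
  for (v in seq_len(tot))
    if (!is.na(tree$parent[v]))
      blen[v] <- tree$height[tree$parent[v]] - tree$height[v]
  B <- sum(blen)
  n_mut <- rpois(1L, mu * B * span_bp)
  n_mut <- min(n_mut, span_bp)  # infinite-sites cap on distinct positions
  if (n_mut == 0L) {
    return(structure(
      list(chromosome = chromosome, positions = integer(0),
           ref_alleles = character(0), alt_alleles = character(0),
           alleles = matrix(0L, n, 0L,
                            dimnames = list(paste0("hap", seq_len(n)), NULL)),
           haplotype_ids = paste0("hap", seq_len(n)),
           sample_populations = NULL),
      class = "haplotype_matrix"))
  }
  pos <- sort(sample.int(span_bp, n_mut, replace = FALSE))
  branch <- sample.int(tot, n_mut, replace = TRUE, prob = blen)
  desc <- descendant_tips(tree)
  al <- matrix(0L, n, n_mut)
  for (s in seq_len(n_mut)) al[desc[[branch[s]]], s] <- 1L
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, n_mut, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1L))
  ids <- paste0("hap", seq_len(n))
  haplotype_matrix(chromosome, pos, ref, unname(alt), al, ids)
}

#' Simulate a non-recombining phased haplotype block
#'
#' Convenience wrapper: [sim_tree()] then [sim_sequences()].
#'
#' @inheritParams sim_tree
#' @inheritParams sim_sequences
#' @return A [haplotype_matrix()] with attribute `"tree"` (the true
#'   genealogy, heights in generations).
#' @export
sim_haplotypes <- function(n, demography, mu, span_bp, seed = NULL,
                           chromosome = "sim1") {
  if (!is.null(seed)) set.seed(seed)
  tree <- sim_tree(n, demography)
  hm <- sim_sequences(tree, mu, span_bp, chromosome = chromosome)
  attr(hm, "tree") <- tree
  hm
}

#' Simulate a block containing one crossover
#'
#' Sites left of `breakpoint_bp` evolve on one genealogy, sites at or right
#' of it on an independent genealogy from the same demography; the true
#' breakpoint is returned for assertions against four-gamete partitioning.
#'
#' @inheritParams sim_haplotypes
#' @param breakpoint_bp Crossover position, `0 < breakpoint_bp < span_bp`.
#' @return A [haplotype_matrix()] with attributes `"breakpoint_bp"`,
#'   `"tree_left"`, `"tree_right"`.
#' @export
sim_recombinant_block <- function(n, demography, mu, span_bp, breakpoint_bp,
                                  seed = NULL, chromosome = "sim1") {
  if (breakpoint_bp <= 0 || breakpoint_bp >= span_bp)
    stop("breakpoint must lie strictly inside the span")
  if (!is.null(seed)) set.seed(seed)
  left_bp <- as.integer(breakpoint_bp)
  right_bp <- as.integer(span_bp) - left_bp
  tl <- sim_tree(n, demography)
  tr <- sim_tree(n, demography)
  hl <- sim_sequences(tl, mu, left_bp, chromosome = chromosome)
  hr <- sim_sequences(tr, mu, right_bp, chromosome = chromosome)
  pos <- c(hl$positions, hr$positions + left_bp)
  al <- cbind(hl$alleles, hr$alleles)
  hm <- if (length(pos) == 0L) hl else
    haplotype_matrix(chromosome, pos,
                     c(hl$ref_alleles, hr$ref_alleles),
                     c(hl$alt_alleles, hr$alt_alleles),
                     al, paste0("hap", seq_len(n)))
  attr(hm, "breakpoint_bp") <- left_bp
  attr(hm, "tree_left") <- tl
  attr(hm, "tree_right") <- tr
  hm
}

#' Simulate two demes under a clean split (no migration)
#'
#' Lineages coalesce within their deme (each of diploid size `ne`) until
#' `split_generations` before present, when the remaining lineages merge
#' into a single ancestral pool of size `ne` and coalesce to the root.
#'
#' @param n_per_deme Haplotypes sampled per deme.
#' @param ne Diploid Ne of each deme and of the ancestral population.
#' @param split_generations Split time in generations (`>= 0`; 0 is
#'   panmixia).
#' @inheritParams sim_sequences
#' @return A [haplotype_matrix()] with `sample_populations` labels
#'   (`"pop1"`/`"pop2"` per haplotype, stored as attribute
#'   `"pop_labels"`) and attribute `"tree"`.
#' @export
sim_two_demes <- function(n_per_deme, ne, split_generations, mu, span_bp,
                          seed = NULL, chromosome = "sim1") {
  if (split_generations < 0) stop("split time must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * n_per_deme
  demog <- .const_demography(ne)
  state <- .new_tree_state(n)
  d1 <- seq_len(n_per_deme)
  d2 <- n_per_deme + seq_len(n_per_deme)
  state <- .coalesce_pool(state, d1, 0, split_generations, demog)
  rem1 <- state$active
  state <- .coalesce_pool(state, d2, 0, split_generations, demog)
  rem2 <- state$active
  state <- .coalesce_pool(state, c(rem1, rem2), split_generations, Inf, demog)
  tree <- .state_to_tree(state, n)
  hm <- sim_sequences(tree, mu, span_bp, chromosome = chromosome)
  attr(hm, "tree") <- tree
  attr(hm, "pop_labels") <- rep(c("pop1", "pop2"), each = n_per_deme)
  hm
}
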