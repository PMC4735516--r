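# Combining block trajectories into the population trajectory. The
# population curve is the vector x minimizing the weighted squared
# Euclidean distance sum_j || diag(w_j) (x - N_j) ||^2 over all block
# vectors N_j; by convexity the unique minimizer is, per time point i,
#   x_i = sum_j w_ji^2 N_ji / sum_j w_ji^2,
# with weights w_ji the inverse posterior SD of block j's Ne at time i.

.traj_matrices <- function(trajectories) {
  if (length(trajectories) == 0L) stop("no block trajectories supplied")
  Tn <- length(trajectories[[1L]]$ne)
  N <- t(vapply(trajectories, function(tr) tr$ne, numeric(Tn)))
  S <- t(vapply(trajectories, function(tr) tr$sd, numeric(Tn)))
  list(N = N, S = S, grid = trajectories[[1L]]$grid,
       ids = vapply(trajectories, function(tr) tr$block_id, character(1L)))
}

#' Inverse-SD weights for trajectory aggregation
#'
#' `w_ji = 1 / sd_ji`. A zero SD (degenerate posterior) is floored at the
#' smallest positive SD observed at that time point; if every block has
#' zero SD at a time point, weights fall back to equal there with a
#' warning.
#'
#' @param trajectories List of [block_trajectory()] objects on one grid.
#' @return Matrix of positive weights, blocks in rows, grid times in
#'   columns.
#' @export
compute_weights <- function(trajectories) {
  tm <- .traj_matrices(trajectories)
  S <- tm$S
  degenerate <- integer(0)
  for (i in seq_len(ncol(S))) {
    zero <- S[, i] <= 0
    if (all(zero)) {
      degenerate <- c(degenerate, i)
      S[, i] <- 1
    } else if (any(zero)) {
      S[zero, i] <- min(S[!zero, i])
    }
  }
  if (length(degenerate))
    warning("all posterior SDs are zero at grid time index(es) ",
            paste(degenerate, collapse = ", "), "; using equal weights there")
  1 / S
}

#' Aggregate block trajectories into a population trajectory
#'
#' Closed-form minimizer of the weighted squared Euclidean distance to all
#' block Ne vectors. With `weight_power = 2` (default) the distance term is
#' `||diag(w_j)(x - N_j)||^2` and the minimizer is
#' `x_i = sum w^2 N / sum w^2`; with `weight_power = 1` the weights are
#' treated as already squared, giving `x_i = sum w N / sum w`.
#'
#' @param trajectories List of [block_trajectory()] objects on one grid.
#' @param weights Weight matrix from [compute_weights()]; `NULL` computes
#'   inverse-SD weights; `"equal"` gives the unweighted mean.
#' @param weight_power 2 (weights enter the objective linearly inside the
#'   norm) or 1 (weights already squared).
#' @return Object of class `population_trajectory` with `ne` per grid time,
#'   `n_blocks`, and the grid.
#' @export
aggregate_trajectories <- function(trajectories, weights = NULL,
                                   weight_power = 2) {
  tm <- .traj_matrices(trajectories)
  if (is.null(weights)) weights <- compute_weights(trajectories)
  if (identical(weights, "equal"))
    weights <- matrix(1, nrow(tm$N), ncol(tm$N))
  if (!all(dim(weights) == dim(tm$N)))
    stop("weight matrix shape must match blocks x grid times")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be finite and positive")
  if (!weight_power %in% c(1, 2)) stop("weight_power must be 1 or 2")
  W <- if (weight_power == 2) weights^2 else weights
  ne <- colSums(W * tm$N) / colSums(W)
  structure(list(ne = ne, n_blocks = nrow(tm$N), grid = tm$grid,
                 weight_power = weight_power),
            class = "population_trajectory")
}

#' Unweighted (equal-weight) population trajectory
#'
#' Per-time arithmetic mean of the block Ne vectors; identical to
#' [aggregate_trajectories()] with all weights equal.
#'
#' @inheritParams aggregate_trajectories
#' @return A `population_trajectory`.
#' @export
aggregate_unweighted <- function(trajectories) {
  aggregate_trajectories(trajectories, weights = "equal")
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat(sprintf("population_trajectory: %d blocks; Ne %.4g (recent) .. %.4g (oldest)\n",
              x$n_blocks, x$ne[1L], x$ne[length(x$ne)]))
  invisible(x)
}

#' Compare aggregated trajectories across block subsets
#'
#' Splits the blocks by `labels`, aggregates each subset, and reports the
#' maximum relative per-time difference between each pair of subset
#' trajectories (`|a - b| / ((a + b) / 2)`), quantifying how similar the
#' subset curves are.
#'
#' @param trajectories List of [block_trajectory()] objects.
#' @param labels Character/factor vector, one subset label per block.
#' @param weights Passed to [aggregate_trajectories()] per subset (`NULL`
#'   recomputes inverse-SD weights within each subset).
#' @return List with `trajectories` (one `population_trajectory` per
#'   non-empty subset) and `max_relative_difference` (named by subset pair;
#'   `NULL` with fewer than two subsets).
#' @export
subset_compare <- function(trajectories, labels, weights = NULL) {
  if (length(labels) != length(trajectories))
    stop("one label per block trajectory required")
  labels <- as.character(labels)
  subsets <- split(seq_along(trajectories), labels)
  empty <- names(subsets)[lengths(subsets) == 0L]
  if (length(empty))
    warning("empty subset(s) omitted: ", paste(empty, collapse = ", "))
  subsets <- subsets[lengths(subsets) > 0L]
  aggs <- lapply(subsets, function(idx)
    aggregate_trajectories(trajectories[idx], weights = weights))
  div <- NULL
  if (length(aggs) >= 2L) {
    nm <- names(aggs)
    pairs <- utils::combn(length(aggs), 2L)
    div <- apply(pairs, 2L, function(p) {
      a <- aggs[[p[1L]]]$ne; b <- aggs[[p[2L]]]$ne
      max(abs(a - b) / ((a + b) / 2))
    })
    names(div) <- apply(pairs, 2L, function(p) paste(nm[p], collapse = "|"))
  }
  list(trajectories = aggs, max_relative_difference = div)
}

#' Write a population trajectory as TSV
#'
#' @param trajectory A `population_trajectory`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_population_tsv <- function(trajectory, path) {
  write.table(data.frame(time_years = trajectory$grid$times,
                         ne = trajectory$ne),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
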