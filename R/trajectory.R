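# Conversion of skyline posteriors from mutational units to calendar years
# and discretization of each block's Ne dynamics onto a fixed year grid.
#
# Unit conventions: skyline heights are substitutions/site; with a strict
# clock of mu substitutions per site per generation and g years per
# generation, years = height / mu * g. Theta is the pairwise-coalescence
# scale, so diploid Ne = theta / (2 mu).

#' Strict-clock scaling constants
#'
#' @param mu Mutation rate per site per generation (default 2.5e-8).
#' @param gen_years Years per generation (default 25).
#' @return Object of class `clock_scaling`.
#' @export
clock_scaling <- function(mu = 2.5e-8, gen_years = 25) {
  if (mu <= 0) stop("mu must be positive")
  if (gen_years <= 0) stop("gen_years must be positive")
  structure(list(mu = mu, gen_years = gen_years), class = "clock_scaling")
}

#' Convert heights in substitutions/site to years (and back)
#'
#' @param height Non-negative height(s) in substitutions/site.
#' @param clock A [clock_scaling()].
#' @return Years before present.
#' @export
rescale_to_years <- function(height, clock) {
  stopifnot(inherits(clock, "clock_scaling"))
  if (any(height < 0)) stop("height must be non-negative")
  height / clock$mu * clock$gen_years
}

#' @rdname rescale_to_years
#' @param years Non-negative years before present.
#' @export
years_to_height <- function(years, clock) {
  stopifnot(inherits(clock, "clock_scaling"))
  if (any(years < 0)) stop("years must be non-negative")
  years / clock$gen_years * clock$mu
}

#' Convert theta to diploid effective population size
#'
#' @param theta Theta on the pairwise-coalescence scale
#'   (substitutions/site).
#' @param clock A [clock_scaling()].
#' @return Diploid Ne (individuals): `theta / (2 mu)`.
#' @export
theta_to_ne <- function(theta, clock) {
  stopifnot(inherits(clock, "clock_scaling"))
  theta / (2 * clock$mu)
}

#' Build the fixed year grid for trajectories
#'
#' @param t_max Oldest grid time in years (default 25000).
#' @param interval Grid spacing in years (default 1000); must divide
#'   `t_max`.
#' @return Object of class `time_grid` with `times` =
#'   `(0, interval, ..., t_max)` and `count = t_max/interval + 1`.
#' @export
make_grid <- function(t_max = 25000, interval = 1000) {
  if (t_max <= 0 || interval <= 0) stop("t_max and interval must be positive")
  if (t_max %% interval != 0) stop("interval must divide t_max")
  times <- seq(0, t_max, by = interval)
  structure(list(t_max = t_max, interval = interval, times = times,
                 count = length(times)),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time_grid: %d points, 0..%g years by %g\n",
              x$count, x$t_max, x$interval))
  invisible(x)
}

#' Discretize a block's skyline posterior onto the year grid
#'
#' Each grid time is mapped to substitutions/site through the inverse clock,
#' every posterior draw is evaluated there with [skyline_at_time()]
#' (piecewise-constant, extrapolating the root-most theta beyond the root),
#' thetas are converted to diploid Ne, and the per-time posterior median
#' (or mean) and SD are recorded. The block's TMRCA is the posterior-median
#' root height in years.
#'
#' @param posterior A non-empty `skyline_posterior`.
#' @param grid A [make_grid()] grid.
#' @param clock A [clock_scaling()].
#' @param block_id Identifier carried through to aggregation.
#' @param point_estimate `"median"` (default) or `"mean"`.
#' @return Object of class `block_trajectory` with fields `block_id`,
#'   `ne` (per grid time), `sd` (posterior SD of Ne per grid time),
#'   `tmrca_years`, and the grid.
#' @export
block_trajectory <- function(posterior, grid, clock = clock_scaling(),
                             block_id = "block1",
                             point_estimate = c("median", "mean")) {
  stopifnot(inherits(grid, "time_grid"))
  point_estimate <- match.arg(point_estimate)
  if (nrow(posterior$theta) == 0L) stop("empty posterior")
  th_times <- years_to_height(grid$times, clock)
  dm <- .skyline_draw_matrix(posterior, th_times)
  ne_draws <- theta_to_ne(dm, clock)
  ne <- if (point_estimate == "median") apply(ne_draws, 2L, median)
        else colMeans(ne_draws)
  sdv <- apply(ne_draws, 2L, sd)
  if (nrow(ne_draws) == 1L) sdv <- rep(0, ncol(ne_draws))
  rh <- posterior$coal_times[, ncol(posterior$coal_times)]
  structure(list(block_id = block_id, ne = ne, sd = sdv,
                 tmrca_years = rescale_to_years(median(rh), clock),
                 grid = grid),
            class = "block_trajectory")
}

#' @export
print.block_trajectory <- function(x, ...) {
  cat(sprintf("block_trajectory %s: Ne %.4g..%.4g over %d grid points, TMRCA %.5g yr\n",
              x$block_id, min(x$ne), max(x$ne), x$grid$count, x$tmrca_years))
  invisible(x)
}

#' Drop blocks with a TMRCA younger than the grid horizon
#'
#' Retains blocks whose posterior-median TMRCA is at least
#' `min_age_years` (boundary inclusive), so every retained block informs
#' the full grid.
#'
#' @param trajectories List of [block_trajectory()] objects.
#' @param min_age_years Minimum TMRCA in years (default 25000).
#' @return The retained list (possibly empty).
#' @export
tmrca_filter <- function(trajectories, min_age_years = 25000) {
  keep <- vapply(trajectories, function(tr) tr$tmrca_years >= min_age_years,
                 logical(1L))
  trajectories[keep]
}

#' Write block trajectories as a TSV table
#'
#' One row per block: `block_id`, `tmrca_years`, `ne_<t>` and `sd_<t>`
#' columns for each grid time.
#'
#' @param trajectories List of [block_trajectory()] objects sharing a grid.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectories_tsv <- function(trajectories, path) {
  if (length(trajectories) == 0L) stop("no trajectories to write")
  g <- trajectories[[1L]]$grid
  rows <- lapply(trajectories, function(tr) {
    data.frame(block_id = tr$block_id, tmrca_years = tr$tmrca_years,
               rbind(setNames(c(tr$ne, tr$sd),
                              c(paste0("ne_", g$times), paste0("sd_", g$times)))),
               check.names = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
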