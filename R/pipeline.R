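# End-to-end orchestration of the three-step strategy: four-gamete block
# partitioning, per-block skyline MCMC with deterministic per-block seeds,
# year-grid trajectories with the TMRCA filter, and weighted aggregation.
# Serial and block-parallel execution are result-identical because each
# block's seed is a pure function of (master seed, block index).

#' Pipeline run configuration
#'
#' Collects every tunable of the full run with its standard default:
#' minimum block length 5000 bp, mutation rate 2.5e-8 per site per
#' generation, 25 years per generation, grid 0..25000 years by 1000,
#' minimum TMRCA 25000 years, inverse-SD weighting.
#'
#' @param vcf Path to a phased VCF (one or more chromosomes).
#' @param out_dir Output directory (created if absent).
#' @param samples Optional sample subset.
#' @param min_length_bp Minimum block length in bp.
#' @param mcmc An [mcmc_config()] template; its seed field is ignored in
#'   favour of per-block seeds derived from `seed`.
#' @param clock A [clock_scaling()].
#' @param grid A [make_grid()] grid.
#' @param min_tmrca_years TMRCA filter threshold in years.
#' @param weight_scheme `"inverse_sd"` or `"equal"`.
#' @param weight_power Passed to [aggregate_trajectories()].
#' @param point_estimate Per-block grid statistic, `"median"` or `"mean"`.
#' @param seed Master seed (integer).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, out_dir, samples = NULL,
                            min_length_bp = 5000,
                            mcmc = mcmc_config(),
                            clock = clock_scaling(),
                            grid = make_grid(),
                            min_tmrca_years = 25000,
                            weight_scheme = c("inverse_sd", "equal"),
                            weight_power = 2,
                            point_estimate = "median",
                            seed = 1L) {
  weight_scheme <- match.arg(weight_scheme)
  structure(list(vcf = vcf, out_dir = out_dir, samples = samples,
                 min_length_bp = min_length_bp, mcmc = mcmc, clock = clock,
                 grid = grid, min_tmrca_years = min_tmrca_years,
                 weight_scheme = weight_scheme, weight_power = weight_power,
                 point_estimate = point_estimate, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Rolling polynomial hash of the serialized configuration; stamps outputs
.config_hash <- function(config) {
  s <- jsonlite::toJSON(list(
    vcf = basename(config$vcf), samples = config$samples,
    min_length_bp = config$min_length_bp,
    mcmc = config$mcmc[c("chain_length", "thin", "burn_in_fraction",
                         "groups", "theta_prior", "theta_bounds",
                         "sample_prior")],
    clock = unclass(config$clock), grid = config$grid[c("t_max", "interval")],
    min_tmrca_years = config$min_tmrca_years,
    weight_scheme = config$weight_scheme,
    weight_power = config$weight_power, seed = config$seed),
    auto_unbox = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Deterministic per-block MCMC seed
#'
#' A pure function of the master seed and block index, so blocks can be
#' processed in any order (or in parallel) with identical results.
#'
#' @param master_seed Integer master seed.
#' @param block_index 1-based block index.
#' @return Integer seed below 2^31.
#' @export
block_seed <- function(master_seed, block_index) {
  as.integer((as.numeric(master_seed) * 1000003 + block_index * 7919) %%
               2147483629)
}

#' Run the full block-skyline pipeline
#'
#' Reads the VCF (per chromosome), partitions each chromosome into
#' four-gamete-compatible blocks, applies the minimum-length filter, runs
#' an independently seeded skyline MCMC per block, discretizes the
#' posteriors onto the year grid, applies the TMRCA filter, and aggregates
#' the surviving block trajectories into the population trajectory.
#' Writes `blocks.bed`, `trajectories.tsv`, `population_trajectory.tsv`,
#' `population_trajectory.json` and `report.json` (counts at every filter
#' stage plus the configuration hash) under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `blocks`, `trajectories` (post-filter),
#'   `population` (a `population_trajectory`), and `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$vcf)) stop("input VCF not found: ", config$vcf)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)

  chroms <- vcf_chromosomes(config$vcf)
  mats <- lapply(chroms, function(ch)
    read_phased_vcf(config$vcf, region = ch, samples = config$samples))

  all_blocks <- list()
  for (mi in seq_along(mats)) {
    bl <- partition_blocks(mats[[mi]])
    bl$matrix_index <- mi
    all_blocks[[mi]] <- bl
  }
  blocks <- do.call(rbind, all_blocks)
  n_blocks_raw <- nrow(blocks)
  blocks <- filter_blocks(blocks, config$min_length_bp)
  n_blocks_len <- nrow(blocks)
  if (n_blocks_len == 0L)
    stop("no blocks survive the minimum-length filter (",
         config$min_length_bp, " bp)")
  blocks$block_id <- paste0(blocks$chromosome, "_b",
                            stats::ave(seq_len(nrow(blocks)),
                                       blocks$chromosome, FUN = seq_along))
  write_blocks_bed(blocks, file.path(config$out_dir, "blocks.bed"))

  trajs <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    hm <- mats[[blocks$matrix_index[i]]]
    aln <- block_alignment(hm, blocks[i, ])
    cfg <- config$mcmc
    cfg$seed <- block_seed(config$seed, i)
    post <- run_skyline_mcmc(aln, cfg,
                             invariant_sites = blocks$length_bp[i] -
                               blocks$n_sites[i])
    trajs[[i]] <- block_trajectory(post, config$grid, config$clock,
                                   block_id = blocks$block_id[i],
                                   point_estimate = config$point_estimate)
  }

  kept <- tmrca_filter(trajs, config$min_tmrca_years)
  if (length(kept) == 0L)
    stop("no blocks survive the TMRCA filter (", config$min_tmrca_years,
         " years); ", length(trajs), " block(s) entered it")
  write_trajectories_tsv(kept, file.path(config$out_dir, "trajectories.tsv"))

  weights <- if (config$weight_scheme == "equal") "equal" else
    compute_weights(kept)
  pop <- aggregate_trajectories(kept, weights = weights,
                                weight_power = config$weight_power)
  write_population_tsv(pop, file.path(config$out_dir,
                                      "population_trajectory.tsv"))
  jsonlite::write_json(
    list(config_hash = hash, time_years = pop$grid$times, ne = pop$ne,
         n_blocks = pop$n_blocks),
    file.path(config$out_dir, "population_trajectory.json"),
    auto_unbox = TRUE, digits = NA)

  report <- list(
    config_hash = hash,
    seed = config$seed,
    n_chromosomes = length(chroms),
    n_sites = sum(vapply(mats, n_sites, integer(1L))),
    n_blocks_partitioned = n_blocks_raw,
    n_blocks_after_length_filter = n_blocks_len,
    n_blocks_after_tmrca_filter = length(kept),
    ne_recent = pop$ne[1L],
    ne_oldest = pop$ne[length(pop$ne)])
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(blocks = blocks, trajectories = kept, population = pop,
                 report = report))
}
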