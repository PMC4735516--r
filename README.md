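# blockskyline

Effective population size (Ne) trajectories from phased autosomal
haplotypes, by combining many small recombination-free windows of the
genome instead of modelling recombination explicitly.

## The problem and the method

Coalescent inference of Ne(t) from sequence data is straightforward on a
non-recombining locus but intractable genome-wide, because genealogies with
recombination over whole chromosomes cannot be sampled for realistic sample
sizes. `blockskyline` takes the divide-and-aggregate route:

1. **Blocks.** Each chromosome is partitioned into *haplotype blocks* —
   maximal contiguous runs of SNPs in which no pair of sites shows all four
   two-locus gametes (the four-gamete test, FGT). Under infinite sites, a
   fourth gamete implies a historical crossover, so each block can be
   treated as crossover-free. Blocks shorter than 5,000 bp are discarded
   (too little genealogical signal).
2. **Per-block skyline.** Each block alignment is analysed with a Bayesian
   skyline coalescent model: an MCMC jointly samples the block genealogy
   and a piecewise-constant population-size function θ(t) whose pieces are
   groups of coalescent intervals, under a JC69 substitution likelihood and
   a strict molecular clock. Heights are in substitutions/site; with a
   mutation rate μ per site per generation and g years per generation,
   times rescale as years = height/μ · g and sizes as Ne = θ/(2μ). Each
   block's posterior is discretized onto a fixed year grid
   T = (0, 1000, …, 25000), giving a vector N_j of per-time median Ne with
   posterior SDs; blocks whose TMRCA is younger than the grid horizon
   (25,000 years) are dropped.
3. **Aggregation.** The population trajectory x̂ minimizes the weighted
   squared Euclidean distance to all block vectors,
   Σ_j ‖diag(w_j)(x − N_j)‖², with weights w_{j,i} = 1/sd_{j,i}. By
   convexity the minimizer is closed-form, per time point i:

   x̂_i = Σ_j w²_{j,i} N_{j,i} / Σ_j w²_{j,i}

   An unweighted (plain mean) variant and subset comparisons (e.g. by
   per-block Weir–Cockerham Fst between two subpopulations, threshold
   0.12%) quantify robustness.

The package also contains a seeded coalescent simulator (piecewise-constant
demography, infinite-sites mutations, optional single crossover and clean
two-deme splits) that generates phased VCF fixtures with known truth; every
statistical claim in the test suite is checked against it or against
brute-force oracles.

## Worked example

Simulate four 5,000-bp non-recombining blocks at constant diploid
Ne = 10,000 for 20 haplotypes, then run the full pipeline:

```r
library(blockskyline)

mats <- lapply(1:4, function(i)
  sim_haplotypes(20, 10000, 2.5e-8, 5000, seed = block_seed(42, i),
                 chromosome = paste0("chr", i)))
write_phased_vcf(mats, "example.vcf")

cfg <- pipeline_config(vcf = "example.vcf", out_dir = "example_run",
                       min_length_bp = 2000,
                       mcmc = mcmc_config(chain_length = 2e5, thin = 100),
                       seed = 42)
res <- run_pipeline(cfg)
str(res$report)
#> List of 9
#>  $ config_hash                 : chr "17cbb13d"
#>  $ seed                        : int 42
#>  $ n_chromosomes               : int 4
#>  $ n_sites                     : int 81
#>  $ n_blocks_partitioned        : int 4
#>  $ n_blocks_after_length_filter: int 4
#>  $ n_blocks_after_tmrca_filter : int 4
#>  $ ne_recent                   : num 10553
#>  $ ne_oldest                   : num 12850
print(res$population)
#> population_trajectory: 4 blocks; Ne 1.055e+04 (recent) .. 1.285e+04 (oldest)
```

The report counts blocks at each filter stage; `ne_recent`/`ne_oldest` are
the aggregated Ne at grid times 0 and 25,000 years — here within ~5–30% of
the simulated constant 10,000, with the trajectory flat to within a factor
of 1.2 (four 5,000-bp blocks carry limited information; precision grows
with block count). `example_run/` holds `blocks.bed`,
`trajectories.tsv` (one row per block: `ne_<t>`, `sd_<t>`, `tmrca_years`),
`population_trajectory.tsv/.json` and `report.json`, all stamped with the
configuration hash.

A thin command-line front end over the same functions lives at
`inst/scripts/blockskyline.R` (subcommands `simulate`, `blocks`, `fst`,
`run`).

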