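Package: blockskyline
Title: Effective Population Size Trajectories from Recombination-Free
    Haplotype Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the trajectory of effective population size (Ne) through
    time from phased autosomal SNP haplotypes. Chromosomes are partitioned
    into crossover-free haplotype blocks with the four-gamete test, each
    block's Ne history is estimated by a Bayesian skyline coalescent MCMC
    under a strict molecular clock and a JC69 substitution likelihood, and
    block trajectories are combined into a population-level Ne(t) curve by
    the closed-form minimizer of a weighted squared Euclidean distance.
    Includes per-block Weir-Cockerham Fst between two subpopulations, and a
    seeded coalescent simulator (piecewise-constant demography, infinite
    sites, optional single crossover and two-deme splits) that generates
    phased VCF fixtures with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
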