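---
title: "Methods: block-wise Bayesian skyline estimation of Ne(t)"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block-wise Bayesian skyline estimation of Ne(t)}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockskyline)
```

## Overview

`blockskyline` estimates the trajectory of effective population size
Ne(t) from phased autosomal SNP haplotypes in three steps: partition each
chromosome into crossover-free haplotype blocks with the four-gamete test;
estimate each block's Ne history with a Bayesian skyline coalescent MCMC;
and combine the block trajectories into a population-level curve by a
closed-form weighted least-squares minimizer. This vignette explains the
models, the parameters that matter, the numerical choices, and what the
validation on simulated data does and does not demonstrate.

## Block identification

Under the infinite-sites assumption, observing all four gametes (00, 01,
10, 11) at a pair of SNPs proves at least one crossover between them.
`partition_blocks()` grows blocks greedily left to right, admitting a
site only while it is pairwise compatible with *every* site already in the
block, and closing the block before the first violating site. This is the
strictest contiguous reading of four-gamete blocking; because the boundary
is forced by the first violation, the partition is unique and ties cannot
arise. Monomorphic columns are compatible with everything and never break
a block. Equality with a brute-force scan over all contiguous windows is
asserted on hundreds of random matrices in the test suite.

Two properties matter for interpretation:

* **Conservative detection.** The FGT can only see crossovers that leave a
  four-gamete footprint; some crossovers go undetected, so blocks are
  "free of *traces* of crossovers", not provably crossover-free. No
  correction is attempted.
* **Localization is right-of-breakpoint.** In a simulated block spliced
  from two independent genealogies, every violating pair spans the
  breakpoint, so the left block always absorbs all left-segment sites and
  the detected boundary falls at or right of the true breakpoint —
  typically within tens of bp when mutation density is high. Tests assert
  exactly this.

Block coordinates are those of the first and last SNP (the only positions
the data defines); blocks shorter than `min_length_bp` (default 5,000 bp)
are discarded because very short blocks carry too little genealogical
signal.

## Per-block skyline model

For a block of n haplotypes the MCMC samples jointly a rooted ultrametric
genealogy (heights in substitutions/site; tips contemporaneous at 0) and a
piecewise-constant population parameter. The n−1 coalescent intervals are
partitioned into m groups; each group g has one θ_g, and an interval with
k lineages and duration t contributes −k(k−1)t/(2θ_g) to the log prior
plus log(k(k−1)/(2θ_g)) at its closing event. θ is on the
pairwise-coalescence scale: the rate for a specific pair is 1/θ, so with a
strict clock of μ substitutions per site per generation, θ = 2·Ne·μ for
diploid Ne. Every factor-of-two convention in the package is anchored to
this identity (the simulator's coalescent rate k(k−1)/(4Ne) per
generation is the same convention expressed in generations).

**Substitution model.** JC69 via Felsenstein pruning with site-pattern
compression. Intraspecific SNP blocks carry essentially no
substitution-model signal, so richer models would add parameters without
information; the likelihood code is an extension point. Block alignments
are SNP-only; `invariant_sites` appends the block's monomorphic positions
(exact under JC69 — only their count matters), keeping branch lengths on
the per-bp scale. The pipeline passes `length_bp − n_snps` automatically.

**Theta hyperprior.** The default is the skyline's exponential Markov
smoothing prior: θ_1 uniform on log θ within `theta_bounds`
(default [1e-6, 10]), and θ_g | θ_{g−1} ~ Exponential(mean θ_{g−1}).
Smoothing matters: on desk-scale blocks (tens of SNPs) some groups contain
almost no coalescent information, and with fully independent priors their
marginal posterior reverts to the prior — whose median Ne under the broad
log-uniform is ~63,000 — grossly inflating poorly informed parts of the
curve. The Markov prior shrinks such groups toward their neighbours. An
independent log-uniform prior per group is available
(`theta_prior = "independent"`) and is used in prior-sampling validation,
where its exactly known marginals make the check sharp.

**Group count.** The default allocates about four coalescent intervals
per group, capped at ten groups: m = max(1, min(10, (n−1) %/% 4)). The
rationale is estimator adequacy rather than convention: with k intervals
in a group the conditional θ posterior is approximately inverse-gamma with
shape k, whose *median* is its scale divided by qgamma(0.5, k) — at k = 2
a structural +19% bias that no chain length removes, at k ≈ 4–5 under 10%.
For large samples (hundreds of haplotypes) the cap keeps the conventional
ten groups with dozens of intervals each, so the rule only changes
small-sample behaviour.

**Proposals.** Per-group θ multipliers; a joint scale of all heights and
θs; uniform node-height slides between each node's children and parent;
root-height multipliers; narrow subtree exchange; moves of one interval
between adjacent groups; and a group-scale move that rescales one group's
θ together with the durations of the intervals it governs through an
order-preserving map of all node heights. The last operator is what makes
θ mix across its many prior decades: it leaves the coalescent density
almost invariant, so it is accepted even for large jumps.

**Initialisation and reproducibility.** The chain starts from a UPGMA tree
on p-distances (with a tiny height ladder so ranked heights are strict)
and θ at half of Watterson's estimate. All randomness flows through R's
RNG: a seed makes runs bit-identical, and extending a chain preserves the
retained-sample prefix. Desk-scale defaults are 2×10⁶ steps, thinning
200, 10% burn-in — enough for the ~20-SNP blocks used in validation;
production runs on long blocks need orders of magnitude more and the
schedule is fully configurable.

## Trajectories, filtering, aggregation

Each posterior draw defines a piecewise-constant θ(t) (right-continuous
looking backwards; beyond the draw's root the root-most θ extends). Grid
times in years (default 0..25,000 by 1,000 — 26 points; deep-time grids
such as 0..300,000 are supported) map to substitutions/site through the
inverse clock; per grid time the posterior median Ne (mean optional) and
the posterior SD are recorded. Blocks whose posterior-median TMRCA is
younger than the grid horizon (boundary inclusive, default 25,000 years)
are removed so every retained block informs the whole grid.

Aggregation minimizes Σ_j ‖diag(w_j)(x − N_j)‖² with w = 1/sd. The unique
minimizer is x̂_i = Σ w² N / Σ w² — an inverse-variance-style pooled
estimate, lying inside the per-time envelope of block values and invariant
to rescaling all weights. Zero SDs (degenerate posteriors) are floored at
the smallest positive SD at that time point; if all SDs vanish the weights
fall back to equal with a warning. Whether the published objective applies
weights inside or outside the square is ambiguous in its source, so
`weight_power` exposes both forms (2: w inside the norm, the default; 1:
weights treated as already squared). Single-pass per-block posterior SDs
are used; an alternative read (95% interval width / 3.92) can be swapped
in by computing weights externally.

`subset_compare()` aggregates user-labelled subsets (gene-overlapping vs
not, Fst above/below a threshold) and reports the maximum relative
per-time difference |a−b|/((a+b)/2) between subset curves. Per-block Fst
uses the Weir–Cockerham variance components in their haploid form (input
is phased haplotypes), combined over polymorphic sites as Σa/Σ(a+b); raw
estimates may be slightly negative and are clamped at zero only for range
reporting and threshold partitioning uses the raw value with a strict
inequality for the high subset.

## The simulator: what validation shows

The simulator generates genealogies under piecewise-constant diploid
demography (rate k(k−1)/(4Ne) per generation, truncated at epoch
boundaries), drops Poisson infinite-sites mutations (positions uniform on
the block span, resampled on collision), and can splice two independent
genealogies at a known breakpoint or impose a clean two-deme split with no
migration. Its calibration is itself tested against closed forms
(E[TMRCA] = 4Ne(1−1/n), Watterson's E[S], pairwise diversity 4Neμ).

Because the simulator realizes exactly the model assumptions (infinite
sites, no gene conversion, no selection, free block independence, perfect
phasing), passing validation demonstrates correctness of the inference
machinery, not robustness to real-data violations: recurrent mutation can
break blocks spuriously, undetected crossovers bias coalescent times, low
coverage depresses rare variants (and thus recent Ne), and μ and
generation-time misspecification rescale the time axis linearly (halving μ
doubles all ages — exposed directly via `clock_scaling`).

Validation problem sizes were chosen to exercise the full pipeline in
minutes on one core: blocks of 5,000 bp with n = 20 haplotypes at
Ne = 10,000 (~18 SNPs each), 20 replicate chains of 2×10⁶ steps for
parameter recovery, and an 8-block end-to-end run that must return a flat
trajectory (max/min < 2.5) under constant truth. With only ~5–7
coalescent events inside the 25,000-year grid window per block, per-block
recent-time estimates are intrinsically noisy; aggregation across blocks
is what stabilizes the curve, and between-block genealogical variance
(not MCMC noise) dominates the remaining scatter.

## Numerical and degenerate-input choices

* Identical haplotypes make UPGMA heights collide; a 1e-9 ladder keeps
  ranked heights strict. Blocks with no variable site run with a warning
  and return a prior-driven posterior.
* Pattern compression includes constant site patterns; no likelihood
  scaling is needed at intraspecific divergences (partials stay far from
  underflow).
* Chains that would retain fewer than 100 samples are refused rather than
  summarized.
* `skyline_at_time` at an interval boundary returns the older interval's
  θ (right-continuity backwards in time); negative times error.
* The TMRCA filter statistic is the posterior median root height —
  "the age of the MRCA" is otherwise unspecified — and the boundary is
  inclusive.
* Per-block MCMC seeds are a pure function of (master seed, block index),
  so serial and block-parallel execution give identical results; outputs
  carry a hash of the full configuration.
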