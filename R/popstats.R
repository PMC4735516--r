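# Weir-Cockerham fixation index between two labeled subpopulations,
# computed from phased haplotype allele counts (haploid variance-component
# form) and combined over a block's polymorphic sites as a ratio of
# averages: Fst = sum(a) / sum(a + b), with a the among-population and b
# the within-population component.

#' Weir-Cockerham Fst for one block between two populations
#'
#' Per polymorphic site, with populations of `n1`, `n2` haplotypes and ALT
#' frequencies `p1`, `p2`:
#' `MSP = sum n_i (p_i - pbar)^2 / (r - 1)`,
#' `MSW = sum n_i p_i (1 - p_i) / sum (n_i - 1)`,
#' `n_c = (N - sum n_i^2 / N) / (r - 1)` with r = 2 populations;
#' the components are `a = (MSP - MSW) / n_c` and `b = MSW`, and the block
#' estimate is `sum(a) / sum(a + b)` over sites. Monomorphic sites carry no
#' information and are excluded.
#'
#' @param x A [haplotype_matrix()].
#' @param block One-row block `data.frame`, or `NULL` for all sites.
#' @param pop_labels Character vector of population labels, either one per
#'   haplotype row or named by sample id (applied to both haplotypes of a
#'   sample); exactly two populations, each with at least 2 haplotypes.
#' @param block_id Identifier for the result.
#' @return Object of class `fst_result`: `block_id`, `fst` (raw estimate,
#'   may be slightly negative), `fst_clamped` (`max(fst, 0)`), `n_sites`
#'   (polymorphic sites used). With no polymorphic site, `fst` is `NA` and
#'   the result is flagged `undefined = TRUE`.
#' @export
weir_cockerham_fst <- function(x, block = NULL, pop_labels,
                               block_id = "block1") {
  cols <- if (is.null(block)) seq_len(n_sites(x)) else
    block$first_site:block$last_site
  labels <- .expand_pop_labels(x, pop_labels)
  pops <- sort(unique(labels))
  if (length(pops) != 2L)
    stop("exactly two populations required, got ", length(pops))
  g1 <- labels == pops[1L]
  g2 <- labels == pops[2L]
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L)
    stop("each population needs at least 2 haplotypes")

  al <- x$alleles[, cols, drop = FALSE]
  c1 <- colSums(al[g1, , drop = FALSE])
  c2 <- colSums(al[g2, , drop = FALSE])
  tot <- c1 + c2
  poly <- tot > 0L & tot < (n1 + n2)
  if (!any(poly)) {
    return(structure(list(block_id = block_id, fst = NA_real_,
                          fst_clamped = NA_real_, n_sites = 0L,
                          undefined = TRUE), class = "fst_result"))
  }
  p1 <- c1[poly] / n1
  p2 <- c2[poly] / n2
  N <- n1 + n2
  r <- 2
  nc <- (N - (n1^2 + n2^2) / N) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / N
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msw <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (N - r)
  a <- (msp - msw) / nc
  b <- msw
  fst <- sum(a) / sum(a + b)
  structure(list(block_id = block_id, fst = fst,
                 fst_clamped = max(fst, 0), n_sites = sum(poly),
                 undefined = FALSE),
            class = "fst_result")
}

.expand_pop_labels <- function(x, pop_labels) {
  H <- n_haplotypes(x)
  if (length(pop_labels) == H && is.null(names(pop_labels)))
    return(as.character(pop_labels))
  if (!is.null(names(pop_labels))) {
    samp <- sub("_[12]$", "", x$haplotype_ids)
    miss <- setdiff(unique(samp), names(pop_labels))
    if (length(miss))
      stop("no population label for sample(s): ", paste(miss, collapse = ", "))
    return(as.character(pop_labels[samp]))
  }
  stop("pop_labels must be per-haplotype or named by sample id")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("fst_result %s: Fst = %.5g over %d polymorphic sites\n",
              x$block_id, x$fst, x$n_sites))
  invisible(x)
}

#' Partition Fst results at a threshold
#'
#' Blocks with Fst strictly greater than the threshold go to `high`, the
#' rest (including the boundary) to `low`, matching a "more than" reading
#' of the genome-average cut-off. Undefined results (no polymorphic sites)
#' are excluded from both lists.
#'
#' @param results List of `fst_result` objects.
#' @param threshold Fst threshold (default 0.0012, i.e. 0.12%).
#' @return List of two lists, `low` (`fst <= threshold`) and `high`
#'   (`fst > threshold`), plus `excluded` (undefined results).
#' @export
partition_by_fst <- function(results, threshold = 0.0012) {
  undef <- vapply(results, function(r) isTRUE(r$undefined), logical(1L))
  ok <- results[!undef]
  fst <- vapply(ok, function(r) r$fst, numeric(1L))
  list(low = ok[fst <= threshold],
       high = ok[fst > threshold],
       excluded = results[undef])
}
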