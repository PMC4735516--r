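# Four-gamete-test (FGT) partitioning of a chromosome into crossover-free
# haplotype blocks. Under infinite sites, observing all four two-locus
# gametes (00, 01, 10, 11) at a pair of SNPs implies at least one historical
# crossover between them; a block is a maximal contiguous run of sites with
# no such pair.

#' Count distinct two-locus gametes
#'
#' @param x A [haplotype_matrix()].
#' @param i,j Distinct site indices (columns of the allele matrix).
#' @return Integer in 1..4: the number of distinct ordered allele pairs
#'   `(allele_i, allele_j)` observed across haplotypes.
#' @export
gamete_count <- function(x, i, j) {
  S <- n_sites(x)
  if (!(i >= 1L && i <= S && j >= 1L && j <= S)) stop("site index out of range")
  if (i == j) stop("gamete_count requires two distinct sites")
  length(unique(2L * x$alleles[, i] + x$alleles[, j]))
}

#' Four-gamete compatibility of a site pair
#'
#' @inheritParams gamete_count
#' @return `TRUE` iff fewer than four distinct gametes are observed, i.e. no
#'   crossover between the two sites is implied under infinite sites.
#' @export
fgt_compatible <- function(x, i, j) gamete_count(x, i, j) < 4L

# all-pairs compatibility of candidate site j against block columns `cols`;
# vectorised over the block
.compatible_with_all <- function(al, cols, j) {
  codes <- al[, cols, drop = FALSE] * 2L + al[, j]
  distinct <- (colSums(codes == 0L) > 0L) + (colSums(codes == 1L) > 0L) +
    (colSums(codes == 2L) > 0L) + (colSums(codes == 3L) > 0L)
  all(distinct < 4L)
}

.block_row <- function(x, first, last) {
  data.frame(chromosome = x$chromosome,
             start_pos = x$positions[first],
             end_pos = x$positions[last],
             first_site = first, last_site = last,
             n_sites = last - first + 1L,
             length_bp = x$positions[last] - x$positions[first] + 1L,
             stringsAsFactors = FALSE)
}

#' Partition a haplotype matrix into FGT-compatible blocks
#'
#' Greedy left-to-right maximal extension: starting at the leftmost
#' unassigned site, the block grows rightward while the candidate site is
#' pairwise FGT-compatible with every site already in the block; on the
#' first violation the block is closed before the violating site and a new
#' block starts there. The result is a complete, non-overlapping,
#' left-to-right partition of the site range. Block coordinates are the
#' positions of the first and last SNP in the block.
#'
#' Monomorphic columns (possible after sample subsetting) are compatible
#' with everything and never break a block.
#'
#' @param x A [haplotype_matrix()] with at least one site.
#' @return A `data.frame` with one row per block: `chromosome`, `start_pos`,
#'   `end_pos` (1-based inclusive), `first_site`, `last_site`, `n_sites`,
#'   `length_bp`.
#' @export
partition_blocks <- function(x) {
  S <- n_sites(x)
  if (S < 1L) stop("partition_blocks needs at least one site")
  al <- x$alleles
  out <- vector("list", 0L)
  first <- 1L
  if (S > 1L) {
    for (j in 2L:S) {
      if (!.compatible_with_all(al, first:(j - 1L), j)) {
        out[[length(out) + 1L]] <- .block_row(x, first, j - 1L)
        first <- j
      }
    }
  }
  out[[length(out) + 1L]] <- .block_row(x, first, S)
  do.call(rbind, out)
}

#' Filter blocks by minimum physical length
#'
#' @param blocks Block `data.frame` from [partition_blocks()].
#' @param min_length_bp Minimum `length_bp` to retain (inclusive);
#'   default 5000.
#' @return The retained rows, order preserved.
#' @export
filter_blocks <- function(blocks, min_length_bp = 5000) {
  if (min_length_bp < 0) stop("min_length_bp must be non-negative")
  blocks[blocks$length_bp >= min_length_bp, , drop = FALSE]
}

#' Extract a block's alignment as nucleotide characters
#'
#' Maps allele 0 to the site's REF nucleotide and allele 1 to its ALT
#' nucleotide, in position order.
#'
#' @param x A [haplotype_matrix()].
#' @param block A one-row block `data.frame` (a row of
#'   [partition_blocks()] output), or `NULL` for all sites.
#' @return Character matrix (haplotypes x sites) of `A`/`C`/`G`/`T`.
#' @export
block_alignment <- function(x, block = NULL) {
  if (is.null(block)) {
    cols <- seq_len(n_sites(x))
  } else {
    if (nrow(block) != 1L) stop("block must be a single row")
    cols <- block$first_site:block$last_site
  }
  if (length(cols) == 0L) stop("empty block")
  al <- x$alleles[, cols, drop = FALSE]
  ref <- x$ref_alleles[cols]
  alt <- x$alt_alleles[cols]
  out <- matrix("", nrow = nrow(al), ncol = ncol(al),
                dimnames = list(x$haplotype_ids, NULL))
  for (k in seq_along(cols))
    out[, k] <- ifelse(al[, k] == 1L, alt[k], ref[k])
  out
}

#' Write a block's haplotype alignment to FASTA
#'
#' One record per haplotype; headers carry the haplotype id; sequence
#' characters are REF where allele = 0 and ALT where allele = 1, in position
#' order.
#'
#' @inheritParams block_alignment
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_block_fasta <- function(x, block, path) {
  aln <- block_alignment(x, block)
  dna <- ape::as.DNAbin(tolower(aln))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Read a haplotype alignment from FASTA
#'
#' @param path FASTA path (e.g. written by [write_block_fasta()]).
#' @return Character matrix (sequences x sites) of upper-case nucleotides.
#' @export
read_block_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  mat <- toupper(as.character(as.matrix(dna)))
  mat
}

#' Write blocks as BED (0-based, half-open)
#'
#' A block with 1-based inclusive coordinates `[start, end]` is written as
#' BED `start-1`, `end`; the name column carries `block<i>`.
#'
#' @param blocks Block `data.frame`, sorted by start.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_blocks_bed <- function(blocks, path) {
  bed <- data.frame(chrom = blocks$chromosome,
                    start = blocks$start_pos - 1L,
                    end = blocks$end_pos,
                    name = paste0("block", seq_len(nrow(blocks))))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of block intervals back to 1-based coordinates
#'
#' @param path BED3+name path.
#' @return `data.frame` with `chromosome`, `start_pos`, `end_pos` (1-based
#'   inclusive), `name`, `length_bp`.
#' @export
read_blocks_bed <- function(path) {
  tb <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  out <- data.frame(chromosome = tb[[1L]],
                    start_pos = tb[[2L]] + 1L,
                    end_pos = tb[[3L]],
                    stringsAsFactors = FALSE)
  out$name <- if (ncol(tb) >= 4L) tb[[4L]] else NA_character_
  out$length_bp <- out$end_pos - out$start_pos + 1L
  out
}
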