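# Phased haplotype matrices: the container every downstream step operates on.
# Coordinates are 1-based inclusive (VCF convention) throughout the package;
# conversion to BED's 0-based half-open scheme happens only at the BED boundary.

#' Construct a phased haplotype matrix
#'
#' A `haplotype_matrix` holds phased biallelic SNP haplotypes over one
#' chromosome: a 0/1 allele matrix with one row per haplotype (two per diploid
#' sample) and one column per site, together with positions and REF/ALT
#' alleles.
#'
#' @param chromosome Chromosome identifier (scalar character).
#' @param positions Integer vector of 1-based site positions, strictly
#'   increasing.
#' @param ref_alleles,alt_alleles Character vectors of single nucleotides
#'   (`A`, `C`, `G`, `T`), one per site.
#' @param alleles Integer matrix of 0 (REF) / 1 (ALT), haplotypes in rows,
#'   sites in columns.
#' @param haplotype_ids Character vector of row identifiers
#'   (`<sample>_1`, `<sample>_2` for VCF input).
#' @param sample_populations Optional named character vector mapping sample
#'   ids to population labels.
#'
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(chromosome, positions, ref_alleles, alt_alleles,
                             alleles, haplotype_ids,
                             sample_populations = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.integer(positions)
  if (length(positions) != ncol(alleles))
    stop("positions length must equal the number of allele columns")
  if (length(positions) > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  if (length(ref_alleles) != length(positions) ||
      length(alt_alleles) != length(positions))
    stop("ref/alt allele vectors must match the number of sites")
  nt <- c("A", "C", "G", "T")
  if (!all(ref_alleles %in% nt) || !all(alt_alleles %in% nt))
    stop("alleles must be single nucleotides A/C/G/T")
  if (any(ref_alleles == alt_alleles))
    stop("REF and ALT must differ at every site")
  if (anyNA(alleles) || !all(alleles %in% c(0L, 1L)))
    stop("allele matrix entries must all be 0 or 1")
  if (length(haplotype_ids) != nrow(alleles))
    stop("haplotype_ids must match the number of haplotype rows")
  rownames(alleles) <- haplotype_ids
  structure(
    list(chromosome = as.character(chromosome)[1L],
         positions = positions,
         ref_alleles = as.character(ref_alleles),
         alt_alleles = as.character(alt_alleles),
         alleles = alleles,
         haplotype_ids = as.character(haplotype_ids),
         sample_populations = sample_populations),
    class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haplotypes x %d sites on %s (%d..%d bp)\n",
              nrow(x$alleles), ncol(x$alleles), x$chromosome,
              if (length(x$positions)) min(x$positions) else NA_integer_,
              if (length(x$positions)) max(x$positions) else NA_integer_))
  invisible(x)
}

#' Number of haplotypes / sites
#' @param x A `haplotype_matrix`.
#' @return Integer count.
#' @export
n_haplotypes <- function(x) nrow(x$alleles)

#' @rdname n_haplotypes
#' @export
n_sites <- function(x) ncol(x$alleles)

.parse_region <- function(region) {
  # "chr" or "chr:start-end", 1-based inclusive
  if (is.null(region)) return(NULL)
  m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1L]]
  if (length(m) == 0L) stop("malformed region: ", region)
  list(chrom = m[2L],
       start = if (nzchar(m[4L])) as.integer(m[4L]) else NA_integer_,
       end   = if (nzchar(m[5L])) as.integer(m[5L]) else NA_integer_)
}

#' Read phased haplotypes from a VCF file
#'
#' Loads a VCF and retains only biallelic SNP records whose genotypes are
#' fully phased (`|` separator) and non-missing for every selected sample.
#' Sites failing any condition are dropped (with a warning for unphased
#' sites) and tallied in the load report attached as attribute
#' `"load_report"`.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param region Optional region string `"chr"` or `"chr:start-end"`
#'   (1-based inclusive).
#' @param samples Optional character vector of sample ids to keep.
#' @param chromosome Deprecated alias for a bare-chromosome `region`.
#'
#' @return A [haplotype_matrix()] with attribute `load_report`, a list with
#'   counts of records seen and dropped by reason.
#' @export
read_phased_vcf <- function(path, region = NULL, samples = NULL,
                            chromosome = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  if (!is.null(chromosome) && is.null(region)) region <- chromosome
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  n_records <- nrow(fix)
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  keep <- rep(TRUE, n_records)
  reg <- .parse_region(region)
  if (!is.null(reg)) {
    keep <- keep & chrom == reg$chrom
    if (!is.na(reg$start)) keep <- keep & pos >= reg$start & pos <= reg$end
  }
  if (length(unique(chrom[keep])) > 1L)
    stop("VCF spans multiple chromosomes; select one with region=")

  snp <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop_nonsnp <- sum(keep & !snp)
  keep <- keep & snp

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_records,
                                     dimnames = list(NULL, colnames(vcf@gt)[-1L]))
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(gt))
    if (length(miss)) stop("samples not in VCF: ", paste(miss, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  gt <- gt[, , drop = FALSE]

  is_missing <- function(g) is.na(g) | g %in% c(".", "./.", ".|.") | grepl("\\.", g)
  unphased <- rowSums(matrix(grepl("/", gt), nrow = n_records)) > 0L
  missing_ <- rowSums(matrix(is_missing(gt), nrow = n_records)) > 0L

  n_drop_unphased <- sum(keep & unphased & !missing_)
  n_drop_missing <- sum(keep & missing_)
  if (n_drop_unphased > 0L)
    warning(n_drop_unphased, " site(s) with unphased genotypes dropped")
  keep <- keep & !unphased & !missing_

  idx <- which(keep)
  if (length(idx) == 0L)
    stop("no biallelic, fully phased SNP sites retained from ", path)
  idx <- idx[order(pos[idx])]

  gtk <- gt[idx, , drop = FALSE]
  n_samp <- ncol(gtk)
  a1 <- substr(gtk, 1L, 1L)
  a2 <- substr(gtk, 3L, 3L)
  if (!all(c(a1, a2) %in% c("0", "1")))
    stop("phased genotypes contain allele codes other than 0/1 at retained sites")

  al <- matrix(0L, nrow = 2L * n_samp, ncol = length(idx))
  hap_ids <- character(2L * n_samp)
  for (s in seq_len(n_samp)) {
    al[2L * s - 1L, ] <- as.integer(a1[, s])
    al[2L * s, ] <- as.integer(a2[, s])
    hap_ids[2L * s - 1L] <- paste0(colnames(gtk)[s], "_1")
    hap_ids[2L * s] <- paste0(colnames(gtk)[s], "_2")
  }

  hm <- haplotype_matrix(chromosome = unique(chrom[idx]),
                         positions = pos[idx],
                         ref_alleles = ref[idx], alt_alleles = alt[idx],
                         alleles = al, haplotype_ids = hap_ids)
  attr(hm, "load_report") <- list(
    n_records = n_records,
    n_retained = length(idx),
    n_dropped_non_snp = n_drop_nonsnp,
    n_dropped_unphased = n_drop_unphased,
    n_dropped_missing = n_drop_missing)
  hm
}

#' Write haplotype matrices as a phased VCF
#'
#' Emits a minimal VCF 4.2 file with one diploid sample per consecutive pair
#' of haplotype rows, genotypes phased with `|`. This is the fixture format
#' the coalescent simulator uses; round-trips through [read_phased_vcf()].
#'
#' @param x A [haplotype_matrix()] with an even number of haplotypes, or a
#'   list of them (one per chromosome, same sample count) for a
#'   multi-chromosome file.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_phased_vcf <- function(x, path) {
  mats <- if (inherits(x, "haplotype_matrix")) list(x) else x
  stopifnot(all(vapply(mats, inherits, logical(1L), "haplotype_matrix")))
  H <- n_haplotypes(mats[[1L]])
  if (H %% 2L != 0L)
    stop("VCF export needs an even number of haplotypes (diploid samples)")
  if (!all(vapply(mats, n_haplotypes, integer(1L)) == H))
    stop("all chromosomes must have the same haplotypes")
  samp <- unique(sub("_[12]$", "", mats[[1L]]$haplotype_ids))
  if (length(samp) != H / 2L)
    samp <- paste0("sample", seq_len(H / 2L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               vapply(mats, function(m) sprintf("##contig=<ID=%s>", m$chromosome),
                      character(1L)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samp), collapse = "\t")), con)
  odd <- seq(1L, H, by = 2L)
  for (m in mats) {
    for (i in seq_len(n_sites(m))) {
      gts <- paste0(m$alleles[odd, i], "|", m$alleles[odd + 1L, i])
      writeLines(paste(c(m$chromosome, m$positions[i], ".",
                         m$ref_alleles[i], m$alt_alleles[i], ".", "PASS", ".",
                         "GT", gts), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Chromosomes present in a VCF file
#'
#' @param path Path to a VCF.
#' @return Character vector of chromosome identifiers in file order.
#' @export
vcf_chromosomes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  unique(vcfR::getCHROM(vcf))
}

#' Read a two-column sample-to-population table
#'
#' @param path TSV with columns `sample_id` and `population` (no header
#'   required; first two columns are used).
#' @return Named character vector: populations named by sample id.
#' @export
read_population_labels <- function(path) {
  tb <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(tb) < 2L) stop("population table needs two columns")
  if (identical(tolower(tb[1L, 1L]), "sample_id")) tb <- tb[-1L, , drop = FALSE]
  setNames(as.character(tb[[2L]]), as.character(tb[[1L]]))
}
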