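# Weir-Cockerham Fst between two labeled subpopulations and threshold
# partitioning.

pop_matrix <- function(rows, n1) {
  hm <- local({
    al <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
    S <- ncol(al)
    haplotype_matrix("chr1", seq_len(S) * 50L, rep("A", S), rep("C", S),
                     al, paste0("h", seq_len(nrow(al))))
  })
  list(hm = hm, labels = rep(c("p1", "p2"), c(n1, nrow(hm$alleles) - n1)))
}

test_that("equal frequencies and sizes give a clamped Fst of zero", {
  pm <- pop_matrix(c("01", "10", "01", "10"), 2)
  r <- weir_cockerham_fst(pm$hm, pop_labels = pm$labels)
  expect_lte(r$fst, 0)
  expect_equal(r$fst_clamped, 0)
  expect_equal(r$n_sites, 2L)
})

test_that("fixed differences at every site give Fst of one", {
  pm <- pop_matrix(c("000", "000", "000", "111", "111", "111"), 3)
  r <- weir_cockerham_fst(pm$hm, pop_labels = pm$labels)
  expect_equal(r$fst, 1)
})

test_that("a three-site configuration matches the hand-evaluated formulas", {
  # pop1: 4 haplotypes, pop2: 6; ALT counts per site 2/1, 1/3, 4/0
  rows <- c("111", "101", "001", "001",                # pop1
            "110", "010", "010", "000", "000", "000")  # pop2
  pm <- pop_matrix(rows, 4)
  r <- weir_cockerham_fst(pm$hm, pop_labels = pm$labels)
  # frozen from a direct evaluation of the published variance components
  expect_equal(r$fst, 0.4848883049, tolerance = 1e-9)
  expect_equal(r$n_sites, 3L)
})

test_that("Fst is invariant to label swap and allele flips", {
  set.seed(71)
  for (rep in 1:10) {
    hm <- rand_hap_matrix(12, 6)
    labels <- rep(c("A", "B"), each = 6)
    r1 <- weir_cockerham_fst(hm, pop_labels = labels)
    r2 <- weir_cockerham_fst(hm, pop_labels = rep(c("B", "A"), each = 6))
    expect_equal(r1$fst, r2$fst, tolerance = 1e-12)
    # flip REF/ALT encoding at a random site
    hm2 <- hm
    i <- sample(6, 1)
    hm2$alleles[, i] <- 1L - hm2$alleles[, i]
    tmp <- hm2$ref_alleles[i]
    hm2$ref_alleles[i] <- hm2$alt_alleles[i]
    hm2$alt_alleles[i] <- tmp
    r3 <- weir_cockerham_fst(hm2, pop_labels = labels)
    expect_equal(r1$fst, r3$fst, tolerance = 1e-12)
  }
})

test_that("monomorphic blocks are flagged undefined", {
  pm <- pop_matrix(c("00", "00", "00", "00"), 2)
  r <- weir_cockerham_fst(pm$hm, pop_labels = pm$labels)
  expect_true(r$undefined)
  expect_true(is.na(r$fst))
})

test_that("population preconditions are enforced", {
  pm <- pop_matrix(c("01", "10", "01", "10"), 2)
  expect_error(weir_cockerham_fst(pm$hm, pop_labels = rep("only", 4)),
               "exactly two")
  expect_error(weir_cockerham_fst(pm$hm,
                                  pop_labels = c("a", "b", "b", "b")),
               "at least 2")
})

test_that("sample-named labels expand to both haplotypes", {
  hm <- sim_haplotypes(8, 5000, 2.5e-8, 10000, seed = 31)
  hm$haplotype_ids <- paste0(rep(paste0("S", 1:4), each = 2), "_", 1:2)
  rownames(hm$alleles) <- hm$haplotype_ids
  named <- c(S1 = "x", S2 = "x", S3 = "y", S4 = "y")
  perhap <- rep(c("x", "y"), each = 4)
  r1 <- weir_cockerham_fst(hm, pop_labels = named)
  r2 <- weir_cockerham_fst(hm, pop_labels = perhap)
  expect_equal(r1$fst, r2$fst)
})

test_that("threshold partition uses strict inequality for the high set", {
  mk <- function(f, id) structure(list(block_id = id, fst = f,
                                       fst_clamped = max(f, 0),
                                       n_sites = 5L, undefined = FALSE),
                                  class = "fst_result")
  res <- list(mk(0.0012, "at"), mk(0.00121, "hi"), mk(-0.01, "neg"),
              mk(0.5, "big"),
              structure(list(block_id = "u", fst = NA_real_,
                             fst_clamped = NA_real_, n_sites = 0L,
                             undefined = TRUE), class = "fst_result"))
  p <- partition_by_fst(res, 0.0012)
  expect_equal(vapply(p$low, function(x) x$block_id, ""), c("at", "neg"))
  expect_equal(vapply(p$high, function(x) x$block_id, ""), c("hi", "big"))
  expect_equal(length(p$low) + length(p$high), 4L)
  expect_length(p$excluded, 1L)
  empty <- partition_by_fst(list())
  expect_length(empty$low, 0L)
  expect_length(empty$high, 0L)
})

test_that("deeper two-deme splits yield larger mean Fst", {
  fst_at_split <- function(split, seeds) {
    mean(vapply(seeds, function(s) {
      hm <- sim_two_demes(8, 5000, split, 1e-7, 20000, seed = s)
      r <- weir_cockerham_fst(hm, pop_labels = attr(hm, "pop_labels"))
      if (is.na(r$fst)) 0 else r$fst
    }, numeric(1)))
  }
  f0 <- fst_at_split(0, 1:25)
  f1 <- fst_at_split(20000, 1:25)
  expect_lt(abs(f0), 0.05)   # panmixia
  expect_gt(f1, f0 + 0.1)    # strong divergence after a deep split
})
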