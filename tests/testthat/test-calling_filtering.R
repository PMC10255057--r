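test_that("read-depth-fraction calling follows the threshold table", {
  # worked values: (19,1) hom-ref, (10,10) het, (5,15) other band -> NA,
  # (1,1) below the depth floor -> NA
  expect_equal(call_genotype(c(19, 10, 5, 1), c(1, 10, 15, 1)),
               c(0L, 1L, NA, NA))
  # boundary cases are inclusive for hom and het windows
  expect_equal(call_genotype(c(18, 2, 12, 8), c(2, 18, 8, 12)),
               c(0L, 2L, 1L, 1L))   # fractions 0.10, 0.90, 0.40, 0.60
  # zero coverage is missing via the depth floor
  expect_equal(call_genotype(0, 0), NA_integer_)
  expect_error(call_genotype(-1, 5), "non-negative")
})

test_that("call_matrix tallies call classes and respects dimensions", {
  # six depth pairs at depth 20 with alt fractions
  # {0.05, 0.5, 0.75, 0.95, 0.45, 0.15}
  alt <- c(1L, 10L, 15L, 19L, 9L, 3L)
  ref <- 20L - alt
  ads <- allele_depth_set(matrix(ref, 1), matrix(alt, 1))
  res <- call_matrix(ads)
  expect_equal(unname(res$genotypes$calls[1, ]), c(0L, 1L, NA, 2L, 1L, NA))
  expect_equal(res$class_counts[["homozygous"]], 2)
  expect_equal(res$class_counts[["heterozygous"]], 2)
  expect_equal(res$class_counts[["other"]], 1)        # 0.75
  expect_equal(res$class_counts[["unclassified"]], 1) # 0.15 gap
  # all-zero depths: everything missing, nothing classified
  zero <- allele_depth_set(matrix(0L, 2, 3), matrix(0L, 2, 3))
  rz <- call_matrix(zero)
  expect_true(all(is.na(rz$genotypes$calls)))
  expect_equal(sum(rz$class_counts[c("homozygous", "heterozygous", "other",
                                     "unclassified")]), 0)
})

test_that("minor allele frequency is computed over typed calls only", {
  expect_equal(compute_maf(toy_gm(matrix(c(0L, 0L, 0L, 0L), 4)))[[1]], 0)
  expect_equal(compute_maf(toy_gm(matrix(c(1L, 1L, 1L, 1L), 4)))[[1]], 0.5)
  # {0, 1, 2, NA}: p_alt = 3/6 -> MAF 0.5
  expect_equal(compute_maf(toy_gm(matrix(c(0L, 1L, 2L, NA), 4)))[[1]], 0.5)
  expect_warning(maf <- compute_maf(toy_gm(matrix(NA_integer_, 3, 1))), "typed")
  expect_true(is.na(maf))
})

test_that("SNP filtering applies strict thresholds in fixed order", {
  # build 5 loci over 10 individuals with MAFs {0.02, 0.05, 0.10, 0.25, 0.30}
  # (20 allele copies -> minor counts {0.4 -> use 20 individuals}); use 10
  # individuals = 20 alleles, minor counts {1, 1, 2, 5, 6} / 20 give
  # {0.05, 0.05, 0.10, 0.25, 0.30}; for 0.02 use 25 individuals instead.
  n <- 50  # 100 allele copies: minor counts {2, 5, 10, 25, 30}
  make_col <- function(minor_alleles, n_missing = 0) {
    d <- integer(n)
    # lay minor alleles as heterozygotes
    d[seq_len(minor_alleles)] <- 1L
    if (n_missing > 0) d[(n - n_missing + 1):n] <- NA_integer_
    d
  }
  # missing rate 0.40 for the last locus: 20 of 50 missing, minor alleles
  # among the 30 typed: 60 alleles * 0.30 = 18
  calls <- cbind(make_col(2), make_col(5), make_col(10), make_col(25),
                 make_col(18, n_missing = 20))
  gm <- toy_gm(calls)
  expect_equal(unname(compute_maf(gm)), c(0.02, 0.05, 0.10, 0.25, 0.30))
  out <- filter_snps(gm, filter_criteria(maf_min = 0.05, missing_max = 0.30))
  expect_equal(attr(out$report, "n_retained"), 2)
  expect_equal(out$genotypes$loci$id, gm$loci$id[3:4])
  # report arithmetic: removals + retained = input
  expect_equal(sum(out$report$n_removed) + attr(out$report, "n_retained"),
               attr(out$report, "n_input"))
  # MAF boundary is strict: exactly 0.05 is removed
  expect_equal(out$report$n_removed[out$report$criterion == "maf"], 2)

  # no-op thresholds are the identity on an all-typed biallelic matrix
  id <- filter_snps(gm[, 1:4], filter_criteria(maf_min = 0, missing_max = 1))
  expect_identical(id$genotypes$calls, gm[, 1:4]$calls)
})

test_that("filtering is idempotent and monotone in the MAF threshold", {
  sim <- simulate_dataset(sim_config(n_groups = 2, group_sizes = c(10, 10),
                                     n_loci = 300, seed = 3,
                                     ancestral_maf_range = c(0.01, 0.5)))
  gm <- call_matrix(sim$depths)$genotypes
  f1 <- filter_snps(gm)
  f2 <- filter_snps(f1$genotypes)
  expect_identical(f2$genotypes$calls, f1$genotypes$calls)
  kept <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(m)
    attr(filter_snps(gm, filter_criteria(maf_min = m))$report, "n_retained"),
    numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("optional heterozygosity cap removes high-Ho loci", {
  calls <- cbind(rep(1L, 10), c(rep(1L, 5), rep(0L, 4), 2L))
  gm <- toy_gm(calls)
  out <- filter_snps(gm, filter_criteria(max_het_rate = 0.8))
  expect_equal(attr(out$report, "n_retained"), 1)
  expect_equal(out$report$n_removed[out$report$criterion == "heterozygosity"], 1)
})
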