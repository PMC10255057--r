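test_that("AMOVA matches the hand-computed two-group example", {
  # 4 individuals, 2 groups of 2, 1 locus with dosages {0,1 | 2,1}
  gm <- toy_gm(matrix(c(0L, 1L, 2L, 1L), 4))
  pm <- popmap(individuals(gm), c("A", "A", "B", "B"))
  res <- amova(gm, pm, n_perm = 0)
  expect_equal(res$table$SS[1:3], c(0.5, 0.5, 1.0))
  expect_equal(res$table$df, c(1, 2, 4, 7))
  expect_equal(res$components, c(0.0625, 0, 0.25))
  expect_equal(res$fst, 0.2)
})

test_that("AMOVA degrees of freedom follow the analyzed design", {
  sim <- simulate_dataset(sim_config(n_loci = 100, seed = 2, n_unknown = 2))
  res <- amova(sim$genotypes, sim$popmap, n_perm = 0)
  # 91 typed individuals in 4 groups: 3 / 87 / 91, total 181
  expect_equal(res$table$df, c(3, 87, 91, 181))
  expect_equal(res$n_individuals, 91)
  # SS additivity
  expect_equal(sum(res$table$SS[1:3]), res$table$SS[4], tolerance = 1e-10)
  # percentages sum to 100
  expect_equal(sum(res$table$percent[1:3]), 100, tolerance = 1e-8)
})

test_that("nested-deviation SS agrees with the pairwise-distance oracle", {
  set.seed(13)
  for (rep in 1:8) {
    n <- sample(6:10, 1)
    L <- sample(5:20, 1)
    G <- sample(2:3, 1)
    grp <- sample(rep(letters[1:G], length.out = n))
    calls <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
    # ensure every group has >= 2 members
    while (min(table(grp)) < 2) grp <- sample(rep(letters[1:G], length.out = n))
    gm <- toy_gm(calls)
    pm <- popmap(individuals(gm), grp)
    res <- amova(gm, pm, n_perm = 0)
    oracle <- amova_ss_oracle(calls, grp)
    expect_equal(res$table$SS[1:3], unname(oracle), tolerance = 1e-8)
  }
})

test_that("AMOVA rejects degenerate designs", {
  gm <- toy_gm(matrix(sample(0:2, 12, replace = TRUE), 4))
  expect_error(amova(gm, popmap(individuals(gm), rep("A", 4)), n_perm = 0),
               "2 groups")
  expect_error(amova(gm, popmap(individuals(gm), c("A", "A", "A", "B")),
                     n_perm = 0),
               "at least 2 individuals")
})

test_that("permutation p-value follows the counting formula and the seed", {
  gm <- toy_gm(matrix(c(0L, 1L, 2L, 1L, 0L, 2L), 6, 5))
  pm <- popmap(individuals(gm), rep(c("A", "B"), each = 3))
  # n_perm = 1: p is either 0.5 or 1.0 by (1 + k) / (1 + 1)
  p1 <- fst_permutation_test(gm, pm, n_perm = 1, seed = 4)
  expect_true(p1 %in% c(0.5, 1.0))
  # deterministic given seed; invariant to individual ordering
  sim <- simulate_dataset(sim_config(n_groups = 2, group_sizes = c(8, 8),
                                     n_loci = 150, seed = 6))
  pa <- fst_permutation_test(sim$genotypes, sim$popmap, n_perm = 49, seed = 9)
  pb <- fst_permutation_test(sim$genotypes, sim$popmap, n_perm = 49, seed = 9)
  expect_identical(pa, pb)
  shuf <- sample(n_individuals(sim$genotypes))
  gshuf <- sim$genotypes[shuf, ]
  pc <- fst_permutation_test(gshuf, sim$popmap, n_perm = 49, seed = 9)
  expect_identical(pa, pc)
  # strongly differentiated groups hit the p floor 1/(1 + n_perm)
  sim2 <- simulate_dataset(sim_config(n_groups = 2, group_sizes = c(10, 10),
                                      n_loci = 300, fst = 0.4, seed = 8))
  p2 <- fst_permutation_test(sim2$genotypes, sim2$popmap, n_perm = 99, seed = 2)
  expect_equal(p2, 0.01)
})

test_that("pairwise Fst hits the limits of differentiation", {
  # two groups fixed for alternate alleles at every locus -> Fst = 1
  calls <- rbind(matrix(0L, 4, 10), matrix(2L, 4, 10))
  gm <- toy_gm(calls)
  pm <- popmap(individuals(gm), rep(c("A", "B"), each = 4))
  pw <- pairwise_fst(gm, pm, n_perm = 0)
  expect_equal(pw$fst["A", "B"], 1)
  expect_equal(pw$fst["A", "A"], 0)
  expect_true(isSymmetric(pw$fst))

  # identically generated groups -> Fst ~ 0
  set.seed(10)
  gf <- matrix(runif(500, 0.2, 0.8), nrow = 1)
  g1 <- sample_genotypes(gf, 30)
  g2 <- sample_genotypes(gf, 30)
  calls2 <- g2$calls
  rownames(calls2) <- paste0("y", seq_len(30))
  both <- geno_matrix(rbind(g1$calls, calls2))
  pmn <- popmap(individuals(both), rep(c("A", "B"), each = 30))
  pw0 <- pairwise_fst(both, pmn, n_perm = 0)
  expect_lt(pw0$fst["A", "B"], 0.01)
})

test_that("simulated differentiation is recovered by pairwise Fst", {
  vals <- unlist(lapply(1:3, function(s) {
    sim <- simulate_dataset(sim_config(n_loci = 1000, fst = 0.05, seed = 40 + s))
    pw <- pairwise_fst(sim$genotypes, sim$popmap, n_perm = 0)
    pw$fst[lower.tri(pw$fst)]
  }))
  expect_true(all(vals > 0.01 & vals < 0.10))
})
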