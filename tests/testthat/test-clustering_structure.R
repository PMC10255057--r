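test_that("Nei distance matches hand-evaluated identities", {
  # A = (0, 2), B = (1, 1): I = 0.5 / sqrt(1 * 0.5), D = -log(I)
  gm <- toy_gm(rbind(c(0L, 2L), c(1L, 1L)))
  D <- nei_distance_matrix(gm)
  expect_equal(D[1, 2], -log(0.5 / sqrt(0.5)), tolerance = 1e-12)
  # identical individuals are at distance zero
  gmi <- toy_gm(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  expect_equal(nei_distance_matrix(gmi)[1, 2], 0)
})

test_that("Nei distance is symmetric with zero diagonal on random data", {
  sim <- simulate_dataset(sim_config(n_groups = 2, group_sizes = c(10, 10),
                                     n_loci = 100, seed = 14,
                                     missing_rate = 0.2))
  gm <- call_matrix(sim$depths)$genotypes
  D <- nei_distance_matrix(gm)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
  # a pair sharing no typed loci is an error naming the pair
  bad <- toy_gm(rbind(c(0L, NA), c(NA, 1L), c(1L, 1L)))
  expect_error(nei_distance_matrix(bad), "no shared typed loci")
})

test_that("neighbor joining recovers closed forms and additive trees", {
  # three-point formula: d(A,B)=2, d(A,C)=3, d(B,C)=4
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_tree(d3)
  bl <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(0.5, 1.5, 2.5))

  # additive 4-taxon matrix from a known tree is recovered exactly
  tree <- ape::read.tree(text = "((a:1,b:2):1.5,(c:0.5,d:3):1);")
  d4 <- ape::cophenetic.phylo(tree)
  rec <- nj_tree(d4)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tree), rec)), 0)
  expect_equal(max(abs(ape::cophenetic.phylo(rec)[rownames(d4), colnames(d4)]
                       - d4)), 0, tolerance = 1e-10)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("locus bootstrap supports are deterministic and saturate on copies", {
  sim <- simulate_dataset(sim_config(n_groups = 2, group_sizes = c(5, 5),
                                     n_loci = 60, fst = 0.3, seed = 15,
                                     missing_rate = 0))
  t1 <- bootstrap_tree(sim$genotypes, n_boot = 25, seed = 99)
  t2 <- bootstrap_tree(sim$genotypes, n_boot = 25, seed = 99)
  expect_identical(t1$node.label, t2$node.label)

  # a matrix of identical duplicated loci: resampling cannot change the tree
  base <- rbind(c(0L, 0L), c(0L, 0L), c(2L, 2L), c(2L, 2L), c(1L, 1L))
  dup <- toy_gm(base[, rep(1:2, 20)])
  tb <- bootstrap_tree(dup, n_boot = 20, seed = 1)
  sup <- as.numeric(tb$node.label[tb$node.label != ""])
  expect_true(all(sup == 100))
})

test_that("well-separated groups earn high bootstrap support", {
  sim <- simulate_dataset(sim_config(n_groups = 2, group_sizes = c(6, 6),
                                     n_loci = 300, fst = 0.3, seed = 23,
                                     missing_rate = 0))
  tb <- bootstrap_tree(sim$genotypes, n_boot = 100, seed = 5)
  # the bipartition splitting the two groups exists and is well supported
  grp1 <- individuals(sim$genotypes)[1:6]
  parts <- ape::prop.part(tb)
  labs <- attr(parts, "labels")
  match_split <- vapply(parts, function(p) {
    tips <- labs[p]
    setequal(tips, grp1) || setequal(tips, setdiff(labs, grp1))
  }, logical(1))
  expect_true(any(match_split))
  node_ids <- which(match_split)  # parts are indexed by internal node order
  sup <- as.numeric(tb$node.label[node_ids])
  expect_true(all(sup[!is.na(sup)] >= 95))
})

test_that("PCA matches a dense eigendecomposition oracle up to sign", {
  set.seed(44)
  calls <- matrix(sample(0:2, 50, replace = TRUE), 5, 10)
  gm <- toy_gm(calls)
  res <- snp_pca(gm)
  Xc <- scale(calls, center = TRUE, scale = FALSE)
  eig <- eigen(tcrossprod(Xc))
  k <- ncol(res$scores)
  for (j in seq_len(k)) {
    oracle <- eig$vectors[, j] * sqrt(eig$values[j])
    expect_lt(min(max(abs(res$scores[, j] - oracle)),
                  max(abs(res$scores[, j] + oracle))), 1e-6)
  }
  # component scores are centered
  expect_lt(max(abs(colSums(res$scores))), 1e-8)
  # identical individuals share coordinates
  gmd <- toy_gm(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L), c(2L, 1L, 0L)))
  rd <- snp_pca(gmd)
  expect_equal(rd$scores[1, ], rd$scores[2, ], tolerance = 1e-10)
  # explained fractions are non-increasing and bounded
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_true(all(res$explained >= 0 & res$explained <= 1))
  expect_error(snp_pca(toy_gm(matrix(1L, 3, 4))), "zero variance")
})

test_that("PCA coordinates are order-invariant up to sign", {
  sim <- simulate_dataset(sim_config(n_groups = 2, group_sizes = c(8, 8),
                                     n_loci = 80, seed = 55))
  r1 <- snp_pca(sim$genotypes, n_comp = 3)
  shuf <- sample(n_individuals(sim$genotypes))
  r2 <- snp_pca(sim$genotypes[shuf, ], n_comp = 3)
  for (j in 1:3) {
    a <- r1$scores[rownames(r2$scores), j]
    b <- r2$scores[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
})

test_that("Evanno delta-K reproduces the worked example and edge cases", {
  mk_runs <- function(means, sds, n = 5, seed = 2) {
    set.seed(seed)
    do.call(rbind, lapply(seq_along(means), function(i) {
      x <- rnorm(n)
      x <- (x - mean(x)) / sd(x) * sds[i] + means[i]
      data.frame(K = i, logL = x)
    }))
  }
  runs <- mk_runs(c(-1000, -900, -880, -875), c(2, 5, 5, 2))
  dk <- evanno_delta_k(runs)
  expect_equal(dk$delta_K[dk$K == 2], 16)
  expect_equal(dk$delta_K[dk$K == 3], 3)
  expect_equal(attr(dk, "optimal_k"), 2)
  expect_true(all(is.na(dk$delta_K[dk$K %in% c(1, 4)])))

  # linear L(K): constant L', zero curvature everywhere
  lin <- mk_runs(c(-100, -90, -80, -70), rep(3, 4))
  dl <- evanno_delta_k(lin)
  expect_equal(dl$delta_K[dl$K %in% 2:3], c(0, 0))

  expect_error(evanno_delta_k(data.frame(K = 1:3, logL = 1:3)), "replicates")
  expect_error(evanno_delta_k(data.frame(K = rep(c(1, 3, 4), each = 2),
                                         logL = rnorm(6))), "contiguous")
})

test_that("tree neighborhoods reflect simulated group structure", {
  sim <- simulate_dataset(sim_config(n_loci = 800, fst = 0.10, seed = 33,
                                     missing_rate = 0))
  D <- nei_distance_matrix(sim$genotypes)
  pm <- sim$popmap
  grp <- pm$group[match(rownames(D), pm$individual)]
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  same <- mean(grp[nn] == grp)
  expect_gte(same, 0.8)
})
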