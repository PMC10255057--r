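# Small in-code fixtures shared across test files.

# A genotype matrix built directly from a dosage matrix.
toy_gm <- function(calls, individuals = NULL) {
  calls <- as.matrix(calls)
  if (is.null(individuals)) individuals <- paste0("s", seq_len(nrow(calls)))
  geno_matrix(calls, individuals = individuals)
}

# Write a minimal hand-formatted VCF (3 samples, GT + AD) and return its path.
write_fixture_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("ch01", "100", "ch01_100", "A", "G", ".", "PASS", ".", "GT:AD",
            "0/0:19,1", "0/1:10,10", "1/1:5,15"), collapse = "\t"),
    paste(c("ch01", "250", "ch01_250", "C", "T", ".", "PASS", ".", "GT:AD",
            "./.:0,0", "1|0:8,9", "0/0:12,0"), collapse = "\t"),
    # multiallelic record, must be dropped
    paste(c("ch02", "40", "ch02_40", "G", "A,T", ".", "PASS", ".", "GT:AD",
            "0/1:5,5,0", "0/0:9,1,0", "1/2:0,4,6"), collapse = "\t")
  )
  writeLines(lines, path)
  path
}

# Brute-force AMOVA oracle: sums of squares from pairwise squared distances
# between allele-level observations (SS_level = sum d^2 / (2 n) identities).
# Complete data only. Returns c(among_groups, among_ind, within_ind).
amova_ss_oracle <- function(calls, grp) {
  n_ind <- nrow(calls)
  L <- ncol(calls)
  # allele-level observation matrix: 2 rows per individual, 0/1 per locus
  A <- matrix(0, nrow = 2 * n_ind, ncol = L)
  for (i in seq_len(n_ind)) {
    d <- calls[i, ]
    A[2 * i - 1, ] <- as.integer(d >= 1)
    A[2 * i, ] <- as.integer(d == 2)
  }
  owner <- rep(seq_len(n_ind), each = 2)
  agrp <- grp[owner]
  d2 <- as.matrix(dist(A))^2
  ss_of <- function(idx) {
    n <- length(idx)
    sum(d2[idx, idx][upper.tri(diag(n))]) / n
  }
  ss_tot <- ss_of(seq_len(2 * n_ind))
  ss_within_ind <- sum(vapply(seq_len(n_ind),
                              function(i) ss_of(which(owner == i)), numeric(1)))
  ss_within_grp <- sum(vapply(unique(agrp),
                              function(g) ss_of(which(agrp == g)), numeric(1)))
  c(among_groups = ss_tot - ss_within_grp,
    among_ind = ss_within_grp - ss_within_ind,
    within_ind = ss_within_ind)
}
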