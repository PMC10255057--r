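#' Simulation configuration for a structured SNP collection
#'
#' Defines the generative model used to emulate a GBS-genotyped germplasm
#' collection: independent biallelic loci, Balding-Nichols group allele
#' frequencies around a uniform ancestral minor-allele frequency, within-group
#' inbreeding, negative-binomial read depth with a per-read miscall rate, and
#' dropout (zero-read) missingness. Defaults mirror a collection of 91 typed
#' individuals in four unequal groups with weak differentiation and a mild
#' heterozygote deficit.
#'
#' @param n_groups number of groups.
#' @param group_sizes individuals per group (all >= 1).
#' @param group_names labels, default `PCNA/PCA/PVNA/PVA` for four groups.
#' @param n_loci number of independent biallelic loci.
#' @param fst Balding-Nichols differentiation parameter, scalar or one value
#'   per group, each in `[0, 1)`.
#' @param inbreeding_f within-group inbreeding coefficient in `[-1, 1]`.
#' @param ancestral_maf_range interval within `(0, 0.5]` from which ancestral
#'   minor-allele frequencies are drawn uniformly.
#' @param mean_depth expected reads per genotype (> 0).
#' @param depth_dispersion negative-binomial size parameter; `Inf` gives
#'   Poisson depth.
#' @param base_error per-read miscall probability in `[0, 1]`.
#' @param missing_rate probability that a genotype receives zero reads.
#' @param n_unknown extra individuals drawn from a random group but labelled
#'   `"Unknown"` in the population map (excluded from group-wise analyses).
#' @param seed RNG seed used by [simulate_dataset()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 4,
                       group_sizes = c(40, 19, 23, 9),
                       group_names = NULL,
                       n_loci = 2000,
                       fst = 0.05,
                       inbreeding_f = 0.1,
                       ancestral_maf_range = c(0.05, 0.5),
                       mean_depth = 25,
                       depth_dispersion = 4,
                       base_error = 0.01,
                       missing_rate = 0.05,
                       n_unknown = 0,
                       seed = 1L) {
  if (is.null(group_names)) {
    group_names <- if (n_groups == 4) c("PCNA", "PCA", "PVNA", "PVA")
                   else paste0("G", seq_len(n_groups))
  }
  if (length(group_sizes) != n_groups) stop("group_sizes length != n_groups")
  if (any(group_sizes < 1)) stop("group_sizes must all be >= 1")
  fst <- rep_len(fst, n_groups)
  if (any(fst < 0 | fst >= 1)) stop("fst must lie in [0, 1)")
  if (inbreeding_f < -1 || inbreeding_f > 1) stop("inbreeding_f outside [-1, 1]")
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (base_error < 0 || base_error > 1) stop("base_error outside [0, 1]")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate outside [0, 1]")
  if (length(ancestral_maf_range) != 2 ||
      ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] > 0.5 ||
      diff(ancestral_maf_range) < 0) {
    stop("ancestral_maf_range must be an interval within (0, 0.5]")
  }
  structure(list(
    n_groups = n_groups, group_sizes = group_sizes, group_names = group_names,
    n_loci = n_loci, fst = fst, inbreeding_f = inbreeding_f,
    ancestral_maf_range = ancestral_maf_range, mean_depth = mean_depth,
    depth_dispersion = depth_dispersion, base_error = base_error,
    missing_rate = missing_rate, n_unknown = n_unknown, seed = seed
  ), class = "sim_config")
}

#' Balding-Nichols group allele frequencies
#'
#' For a locus with ancestral alternate-allele frequency `p`, each group's
#' frequency is drawn from `Beta(p (1 - Fst) / Fst, (1 - p)(1 - Fst) / Fst)`,
#' giving mean `p` and variance `Fst * p * (1 - p)`. When `fst = 0` the group
#' frequency equals `p` exactly.
#'
#' @param ancestral_p numeric vector of ancestral frequencies in `(0, 1)`,
#'   one per locus.
#' @param fst differentiation parameter(s): scalar or one per group, each in
#'   `[0, 1)`.
#' @param n_groups number of groups.
#' @return numeric matrix, `n_groups` rows x `length(ancestral_p)` columns.
#' @export
sample_group_freqs <- function(ancestral_p, fst, n_groups) {
  if (any(ancestral_p <= 0 | ancestral_p >= 1)) {
    stop("ancestral frequencies must lie strictly in (0, 1)")
  }
  fst <- rep_len(fst, n_groups)
  if (any(fst >= 1)) stop("fst = 1 gives a degenerate Beta distribution")
  if (any(fst < 0)) stop("fst must be >= 0")
  L <- length(ancestral_p)
  out <- matrix(NA_real_, nrow = n_groups, ncol = L)
  for (g in seq_len(n_groups)) {
    if (fst[g] == 0) {
      out[g, ] <- ancestral_p
    } else {
      k <- (1 - fst[g]) / fst[g]
      out[g, ] <- stats::rbeta(L, shape1 = ancestral_p * k,
                               shape2 = (1 - ancestral_p) * k)
    }
  }
  out
}

#' Sample codominant genotypes under inbreeding
#'
#' Per individual and locus, genotype dosages follow the inbreeding-adjusted
#' Hardy-Weinberg law with group alternate-allele frequency `p`, `q = 1 - p`
#' and inbreeding coefficient `F`:
#' `P(2) = p^2 + F p q`, `P(1) = 2 p q (1 - F)`, `P(0) = q^2 + F p q`.
#'
#' @param group_freqs matrix from [sample_group_freqs()] (groups x loci).
#' @param group_sizes individuals per group.
#' @param inbreeding_f inbreeding coefficient `F`.
#' @param group_names optional group labels (used in individual names).
#' @return a [geno_matrix()] with `sum(group_sizes)` individuals; individual
#'   order follows groups.
#' @export
sample_genotypes <- function(group_freqs, group_sizes, inbreeding_f = 0,
                             group_names = NULL) {
  G <- nrow(group_freqs); L <- ncol(group_freqs)
  if (length(group_sizes) != G) stop("group_sizes length != nrow(group_freqs)")
  if (any(group_freqs < 0 | group_freqs > 1)) stop("frequencies outside [0, 1]")
  if (is.null(group_names)) group_names <- paste0("G", seq_len(G))
  N <- sum(group_sizes)
  calls <- matrix(NA_integer_, nrow = N, ncol = L)
  row0 <- 0L
  for (g in seq_len(G)) {
    p <- group_freqs[g, ]; q <- 1 - p
    p2 <- p^2 + inbreeding_f * p * q
    p1 <- 2 * p * q * (1 - inbreeding_f)
    p0 <- q^2 + inbreeding_f * p * q
    if (any(p0 < -1e-12 | p1 < -1e-12 | p2 < -1e-12)) {
      stop("inbreeding_f makes a genotype probability negative at some locus")
    }
    n <- group_sizes[g]
    u <- matrix(stats::runif(n * L), nrow = n)
    cp2 <- matrix(pmax(p2, 0), nrow = n, ncol = L, byrow = TRUE)
    cp21 <- matrix(pmax(p2, 0) + pmax(p1, 0), nrow = n, ncol = L, byrow = TRUE)
    d <- matrix(0L, nrow = n, ncol = L)
    d[u < cp21] <- 1L
    d[u < cp2] <- 2L
    calls[row0 + seq_len(n), ] <- d
    row0 <- row0 + n
  }
  inds <- unlist(lapply(seq_len(G), function(g)
    sprintf("%s_%02d", group_names[g], seq_len(group_sizes[g]))))
  geno_matrix(calls, individuals = inds)
}

#' Sample sequencing read depths given true genotypes
#'
#' Total depth per cell is negative binomial with mean `mean_depth` and size
#' `depth_dispersion` (Poisson when `depth_dispersion = Inf`), set to zero
#' with probability `missing_rate`. Alternate reads are binomial with success
#' probability `base_error`, `0.5`, or `1 - base_error` for true dosage 0, 1,
#' 2 respectively.
#'
#' @param gm a [geno_matrix()] of true genotypes (no missing calls).
#' @param mean_depth,depth_dispersion,base_error,missing_rate see
#'   [sim_config()].
#' @return an [allele_depth_set()] with the same individuals and loci.
#' @export
sample_allele_depths <- function(gm, mean_depth = 25, depth_dispersion = 4,
                                 base_error = 0.01, missing_rate = 0.05) {
  d <- gm$calls
  if (anyNA(d)) stop("true genotypes must be complete")
  n <- length(d)
  total <- if (is.finite(depth_dispersion)) {
    stats::rnbinom(n, size = depth_dispersion, mu = mean_depth)
  } else {
    stats::rpois(n, lambda = mean_depth)
  }
  if (missing_rate > 0) {
    total[stats::runif(n) < missing_rate] <- 0L
  }
  mu <- c(base_error, 0.5, 1 - base_error)[d + 1L]
  alt <- stats::rbinom(n, size = total, prob = mu)
  ref <- total - alt
  allele_depth_set(matrix(ref, nrow = nrow(d)), matrix(alt, nrow = nrow(d)),
                   individuals = rownames(d), loci = gm$loci)
}

#' Simulate a complete structured SNP dataset
#'
#' Composes [sample_group_freqs()], [sample_genotypes()] and
#' [sample_allele_depths()] under one configuration. Deterministic given
#' `config$seed`. Loci are placed at random positions on 15 chromosomes with
#' identifiers of the form `ch07_1234567`.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset` with elements `config`, `ancestral_p`,
#'   `group_freqs`, `genotypes` (true calls), `depths` and `popmap`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_loci
  maf <- stats::runif(L, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
  # randomly orient: ancestral ALT frequency is maf or 1 - maf
  p <- ifelse(stats::runif(L) < 0.5, maf, 1 - maf)
  gf <- sample_group_freqs(p, config$fst, config$n_groups)

  sizes <- config$group_sizes
  names <- config$group_names
  unknown_src <- integer(0)
  if (config$n_unknown > 0) {
    # unknown-type individuals belong to a real (random) group genetically
    unknown_src <- sample.int(config$n_groups, config$n_unknown, replace = TRUE)
  }
  gm <- sample_genotypes(gf, sizes, config$inbreeding_f, names)
  groups <- rep(names, sizes)
  if (config$n_unknown > 0) {
    extra <- sample_genotypes(gf[unknown_src, , drop = FALSE],
                              rep(1L, config$n_unknown), config$inbreeding_f,
                              sprintf("Unk_%02d", seq_len(config$n_unknown)))
    calls <- rbind(gm$calls, extra$calls)
    rownames(calls) <- c(individuals(gm),
                         sprintf("Unknown_%02d", seq_len(config$n_unknown)))
    gm <- geno_matrix(calls)
    groups <- c(groups, rep("Unknown", config$n_unknown))
  }
  chrom <- sprintf("ch%02d", sample.int(15, L, replace = TRUE))
  pos <- sample.int(3e7, L)
  o <- order(chrom, pos)
  loci <- data.frame(chrom = chrom[o], pos = pos[o],
                     ref = sample(c("A", "C", "G", "T"), L, replace = TRUE),
                     stringsAsFactors = FALSE)
  loci$alt <- vapply(loci$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  gm <- geno_matrix(gm$calls[, o, drop = FALSE][, , drop = FALSE],
                    individuals = individuals(gm), loci = loci)
  p <- p[o]; gf <- gf[, o, drop = FALSE]
  depths <- sample_allele_depths(gm, config$mean_depth, config$depth_dispersion,
                                 config$base_error, config$missing_rate)
  structure(list(
    config = config,
    ancestral_p = p,
    group_freqs = gf,
    genotypes = gm,
    depths = depths,
    popmap = popmap(individuals(gm), groups)
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", n_individuals(x$genotypes), "individuals (",
      paste(x$config$group_sizes, collapse = "/"), "+",
      x$config$n_unknown, "unknown ) x", n_loci(x$genotypes), "loci\n")
  invisible(x)
}
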