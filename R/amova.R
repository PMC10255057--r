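#' Three-level analysis of molecular variance (AMOVA)
#'
#' Partitions allelic variance among groups, among individuals within groups,
#' and within individuals (between an individual's two alleles) for
#' codominant biallelic genotypes. Each typed individual contributes two
#' allelic observations per locus (dosage `d` maps to alleles summing to
#' `d`). Sums of squares are computed per locus as nested deviations with
#' per-locus typed counts and summed over loci; variance components are
#' solved per locus from the expected mean squares with unequal-size
#' (`n0`-style) coefficients and summed. Fixation indices are
#' `Fst = Va / (Va + Vb + Vc)`, `Fis = Vb / (Vb + Vc)`,
#' `Fit = (Va + Vb) / (Va + Vb + Vc)`.
#'
#' Missing calls contribute no alleles at their locus; loci informative in
#' fewer than two groups, or with no within-group replication, are skipped.
#' Degrees of freedom are reported from the analyzed design: `G - 1`,
#' `N - G`, `N` and total `2N - 1` for `N` individuals in `G` groups.
#'
#' @param gm a [geno_matrix()].
#' @param pm a [popmap()]; unknown-type individuals are excluded.
#' @param truncate_negative floor negative variance components at zero for
#'   percentages and fixation indices (default `TRUE`; a message reports when
#'   it triggers).
#' @param n_perm permutations of individuals among groups for the Fst
#'   p-value; `0` skips the test. Default 999.
#' @param seed RNG seed for the permutation test.
#' @return object of class `amova_result`: list with `table` (source, df,
#'   SS, MS, variance, percent), `fst`, `fis`, `fit`, `p_value`, `n_perm`,
#'   `seed`, `n_individuals`, `n_groups`, `components` (untruncated Va, Vb,
#'   Vc).
#' @export
amova <- function(gm, pm, truncate_negative = TRUE, n_perm = 999, seed = 1L) {
  prep <- amova_prepare(gm, pm)
  if (prep$G < 2) stop("AMOVA needs at least 2 groups with known type")
  if (any(table(prep$grp) < 2)) stop("every group needs at least 2 individuals")
  obs <- amova_components(prep$X0, prep$M, prep$grp, prep$sswi)

  N <- length(prep$grp); G <- prep$G
  df <- c(G - 1, N - G, N)
  ss <- obs$SS
  ms <- ss / df
  V <- c(obs$Va, obs$Vb, obs$Vc)
  Vt <- V
  if (truncate_negative && any(V < 0)) {
    message("negative variance component(s) floored at zero: ",
            paste(c("Va", "Vb", "Vc")[V < 0], collapse = ", "))
    Vt <- pmax(V, 0)
  }
  tot <- sum(Vt)
  fst <- if (tot > 0) Vt[1] / tot else NA_real_
  fis <- if (sum(Vt[2:3]) > 0) Vt[2] / sum(Vt[2:3]) else NA_real_
  fit <- if (tot > 0) sum(Vt[1:2]) / tot else NA_real_

  p_value <- NA_real_
  if (n_perm > 0) {
    p_value <- fst_permutation_test(gm, pm, n_perm = n_perm, seed = seed,
                                    truncate_negative = truncate_negative,
                                    observed_fst = fst, prep = prep)
  }
  tab <- data.frame(
    source = c("Among groups", "Among individuals", "Within individuals", "Total"),
    df = c(df, 2 * N - 1),
    SS = c(ss, sum(ss)),
    MS = c(ms, NA_real_),
    variance = c(Vt, sum(Vt)),
    percent = if (tot > 0) c(100 * Vt / tot, 100) else rep(NA_real_, 4),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, fst = fst, fis = fis, fit = fit,
                 p_value = p_value, n_perm = n_perm, seed = seed,
                 n_individuals = N, n_groups = G, components = V),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA:", x$n_individuals, "individuals in", x$n_groups, "groups\n")
  print(x$table, digits = 6, row.names = FALSE)
  cat(sprintf("Fst = %.5f  Fis = %.5f  Fit = %.5f\n", x$fst, x$fis, x$fit))
  if (!is.na(x$p_value)) {
    cat(sprintf("Permutation p(Fst) = %.5g (%d permutations)\n",
                x$p_value, x$n_perm))
  }
  invisible(x)
}

# Shared precomputation: dosage matrix restricted to analyzable individuals,
# zero-filled copy, typed mask, group factor, per-locus within-individual SS.
amova_prepare <- function(gm, pm) {
  pa <- analyzable(pm)
  keep <- intersect(individuals(gm), pa$individual)
  if (length(keep) < 4) stop("too few analyzable individuals")
  X <- gm$calls[keep, , drop = FALSE]
  grp <- factor(pa$group[match(keep, pa$individual)])
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0L
  storage.mode(X0) <- "double"
  storage.mode(M) <- "double"
  sswi <- 0.5 * colSums(X == 1L, na.rm = TRUE)
  list(X0 = X0, M = M, grp = grp, sswi = sswi, G = nlevels(grp))
}

# Core per-locus nested ANOVA, vectorised over loci. Returns summed SS
# (among groups, among individuals within groups, within individuals) and
# summed per-locus variance components.
amova_components <- function(X0, M, grp, sswi) {
  S <- rowsum(X0, grp, reorder = FALSE)      # G x L allele-dosage sums
  n <- rowsum(M, grp, reorder = FALSE)       # G x L typed counts
  Tl <- colSums(S)
  Nl <- colSums(n)
  Gl <- colSums(n > 0)
  ss_tot <- Tl - Tl^2 / (2 * Nl)
  r <- S^2 / (2 * n)
  r[n == 0] <- 0
  ss_ag <- colSums(r) - Tl^2 / (2 * Nl)
  ss_ai <- ss_tot - ss_ag - sswi

  df_ag <- Gl - 1
  df_ai <- Nl - Gl
  ok <- Gl >= 2 & df_ai >= 1 & Nl >= 2
  n0 <- (2 * Nl - colSums((2 * n)^2) / (2 * Nl)) / pmax(df_ag, 1)

  vc_l <- sswi / Nl
  ms_ai <- ss_ai / df_ai
  vb_l <- (ms_ai - vc_l) / 2
  va_l <- (ss_ag / pmax(df_ag, 1) - ms_ai) / n0

  list(
    SS = c(sum(ss_ag[ok]), sum(ss_ai[ok]), sum(sswi[ok])),
    Va = sum(va_l[ok]), Vb = sum(vb_l[ok]), Vc = sum(vc_l[ok]),
    n_loci_used = sum(ok)
  )
}

# Fst from summed components for a given grouping (used by the permutation
# loop); NA when the total component is not positive.
amova_fst_value <- function(X0, M, grp, sswi, truncate_negative = TRUE) {
  cm <- amova_components(X0, M, grp, sswi)
  V <- c(cm$Va, cm$Vb, cm$Vc)
  if (truncate_negative) V <- pmax(V, 0)
  tot <- sum(V)
  if (tot <= 0) return(NA_real_)
  V[1] / tot
}

#' Permutation test for the among-group fixation index
#'
#' Permutes whole individuals among groups (preserving group sizes),
#' recomputes Fst for each permutation, and reports
#' `p = (1 + #\{Fst_perm >= Fst_obs\}) / (1 + n_perm)`. Deterministic given
#' `seed` and invariant to individual ordering.
#'
#' @param gm a [geno_matrix()].
#' @param pm a [popmap()].
#' @param n_perm number of permutations (default 999, giving a p-value floor
#'   of 0.001).
#' @param seed RNG seed.
#' @param truncate_negative floor negative components at zero (as in
#'   [amova()]).
#' @param observed_fst,prep internal fast-path arguments; normally omitted.
#' @return permutation p-value.
#' @export
fst_permutation_test <- function(gm, pm, n_perm = 999, seed = 1L,
                                 truncate_negative = TRUE,
                                 observed_fst = NULL, prep = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(prep)) prep <- amova_prepare(gm, pm)
  # order-invariant: permute within a canonical individual ordering
  ord <- order(rownames(prep$X0))
  X0 <- prep$X0[ord, , drop = FALSE]
  M <- prep$M[ord, , drop = FALSE]
  grp <- prep$grp[ord]
  sswi <- prep$sswi
  if (is.null(observed_fst)) {
    observed_fst <- amova_fst_value(X0, M, grp, sswi, truncate_negative)
  }
  set.seed(seed)
  N <- length(grp)
  ge <- vapply(seq_len(n_perm), function(i) {
    amova_fst_value(X0, M, grp[sample.int(N)], sswi, truncate_negative)
  }, numeric(1))
  (1 + sum(ge >= observed_fst, na.rm = TRUE)) / (1 + n_perm)
}

#' Pairwise Fst matrix with permutation p-values
#'
#' For each unordered pair of groups, a two-group AMOVA restricted to the
#' pair's individuals yields Fst and a permutation p-value.
#'
#' @param gm a [geno_matrix()].
#' @param pm a [popmap()].
#' @param n_perm permutations per pair (default 999); `0` skips p-values.
#' @param seed RNG seed.
#' @param truncate_negative as in [amova()].
#' @return object of class `pairwise_fst`: list with symmetric matrix `fst`
#'   (diagonal 0) and matrix `p_value`.
#' @export
pairwise_fst <- function(gm, pm, n_perm = 999, seed = 1L,
                         truncate_negative = TRUE) {
  groups <- popmap_groups(pm)
  G <- length(groups)
  if (G < 2) stop("need at least 2 groups")
  fst <- matrix(0, G, G, dimnames = list(groups, groups))
  pv <- matrix(NA_real_, G, G, dimnames = list(groups, groups))
  pa <- analyzable(pm)
  for (i in seq_len(G - 1)) for (j in (i + 1):G) {
    pair <- pa[pa$group %in% groups[c(i, j)], , drop = FALSE]
    sub_pm <- popmap(pair$individual, pair$group)
    res <- amova(gm, sub_pm, truncate_negative = truncate_negative,
                 n_perm = n_perm, seed = seed + i * G + j)
    fst[i, j] <- fst[j, i] <- res$fst
    pv[i, j] <- pv[j, i] <- res$p_value
  }
  structure(list(fst = fst, p_value = pv, n_perm = n_perm, seed = seed),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, ...) {
  cat("Pairwise Fst (lower triangle) / permutation p (upper triangle):\n")
  m <- x$fst
  m[upper.tri(m)] <- x$p_value[upper.tri(m)]
  print(round(m, 5))
  invisible(x)
}
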