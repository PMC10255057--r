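#' Read-depth-fraction genotype calling thresholds
#'
#' A genotype is called from its reference/alternate read counts by the
#' major-allele read fraction: homozygous when one allele carries at least
#' `hom_fraction` of the reads, heterozygous when the alternate fraction lies
#' in `[het_low, het_high]`, and missing otherwise ("other"-type calls and
#' cells below `min_depth` reads). Fractions in the unclassified bands between
#' the heterozygote window and the homozygote floor are treated as missing.
#'
#' @param min_depth minimum total reads to attempt a call (default 3).
#' @param hom_fraction major-allele read-fraction floor for a homozygous call
#'   (default 0.90; must exceed 0.5).
#' @param het_low,het_high alternate-fraction window for a heterozygous call
#'   (defaults 0.40 and 0.60).
#' @return list of class `call_thresholds`.
#' @export
call_thresholds <- function(min_depth = 3, hom_fraction = 0.90,
                            het_low = 0.40, het_high = 0.60) {
  if (hom_fraction <= 0.5 || hom_fraction > 1) stop("hom_fraction must be in (0.5, 1]")
  if (het_low < 0 || het_low >= het_high || het_high > 1) {
    stop("need 0 <= het_low < het_high <= 1")
  }
  if (het_high >= hom_fraction) stop("het_high must be below hom_fraction")
  if (min_depth < 1) stop("min_depth must be >= 1")
  structure(list(min_depth = min_depth, hom_fraction = hom_fraction,
                 het_low = het_low, het_high = het_high),
            class = "call_thresholds")
}

#' Call genotypes from reference/alternate read counts
#'
#' Vectorised over cells. With `a = alt / (ref + alt)`:
#' total `< min_depth` -> `NA`; `a >= hom_fraction` -> 2;
#' `a <= 1 - hom_fraction` -> 0; `het_low <= a <= het_high` -> 1; any other
#' fraction -> `NA`.
#'
#' @param ref_count,alt_count non-negative integer vectors of equal length.
#' @param thresholds a [call_thresholds()].
#' @return integer vector of dosages in `{0, 1, 2, NA}`.
#' @examples
#' call_genotype(c(19, 10, 5, 1), c(1, 10, 15, 1))
#' @export
call_genotype <- function(ref_count, alt_count, thresholds = call_thresholds()) {
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative")
  }
  total <- ref_count + alt_count
  a <- ifelse(total > 0, alt_count / total, NA_real_)
  out <- rep(NA_integer_, length(total))
  ok <- total >= thresholds$min_depth
  eps <- 1e-9   # read fractions are ratios of small integers; guard rounding
  out[ok & a >= thresholds$hom_fraction - eps] <- 2L
  out[ok & a <= 1 - thresholds$hom_fraction + eps] <- 0L
  out[ok & a >= thresholds$het_low - eps & a <= thresholds$het_high + eps] <- 1L
  out
}

#' Call a whole allele-depth set and tally call classes
#'
#' Applies [call_genotype()] element-wise and counts, among cells at or above
#' the depth floor, homozygous (dosage 0 or 2), heterozygous (dosage 1),
#' "other"-band calls (alternate read fraction in `[0.2, 0.4)` or
#' `(0.6, 0.9)` under default thresholds) and unclassified fractions (the
#' band between the homozygote floor and the "other" band, e.g.
#' `(0.1, 0.2)`). Both of the latter become missing genotypes.
#'
#' @param depths an [allele_depth_set()].
#' @param thresholds a [call_thresholds()].
#' @return list with `genotypes` (a [geno_matrix()]) and `class_counts`
#'   (named vector: homozygous, heterozygous, other, unclassified,
#'   low_depth).
#' @export
call_matrix <- function(depths, thresholds = call_thresholds()) {
  stopifnot(inherits(depths, "allele_depth_set"))
  ref <- depths$ref; alt <- depths$alt
  d <- call_genotype(as.vector(ref), as.vector(alt), thresholds)
  total <- as.vector(ref) + as.vector(alt)
  a <- ifelse(total > 0, as.vector(alt) / total, NA_real_)
  deep <- total >= thresholds$min_depth
  other_band <- (a >= 0.2 & a < thresholds$het_low) |
    (a > thresholds$het_high & a < thresholds$hom_fraction)
  counts <- c(
    homozygous = sum(deep & !is.na(d) & d != 1L),
    heterozygous = sum(deep & !is.na(d) & d == 1L),
    other = sum(deep & is.na(d) & other_band),
    unclassified = sum(deep & is.na(d) & !other_band),
    low_depth = sum(!deep)
  )
  calls <- matrix(d, nrow = nrow(ref))
  gm <- geno_matrix(calls, individuals = rownames(ref), loci = depths$loci)
  list(genotypes = gm, class_counts = counts)
}

#' Per-locus minor allele frequency
#'
#' Allele frequencies are computed from dosages over non-missing calls:
#' `p_alt = sum(dosage) / (2 * N_typed)`; MAF is `min(p_alt, 1 - p_alt)`.
#'
#' @param gm a [geno_matrix()].
#' @param individuals optional subset of individuals (labels or indices).
#' @return numeric vector of MAF per locus, in `[0, 0.5]`; `NA` for loci with
#'   no typed calls in the subset (flagged via a warning).
#' @export
compute_maf <- function(gm, individuals = NULL) {
  calls <- gm$calls
  if (!is.null(individuals)) calls <- calls[individuals, , drop = FALSE]
  n <- colSums(!is.na(calls))
  p <- colSums(calls, na.rm = TRUE) / (2 * n)
  if (any(n == 0)) {
    warning(sum(n == 0), " locus/loci with no typed calls; MAF set to NA")
    p[n == 0] <- NA_real_
  }
  pmin(p, 1 - p)
}

#' SNP filtering criteria
#'
#' Loci are retained when they are biallelic, their minor allele frequency
#' strictly exceeds `maf_min`, their missing-call fraction is strictly below
#' `missing_max`, and (optionally) their observed heterozygosity does not
#' exceed `max_het_rate`. Criteria are applied in that fixed order for the
#' removal report.
#'
#' @param maf_min MAF floor, strict `>` (default 0.05).
#' @param missing_max missing-fraction ceiling, strict `<` (default 0.30).
#' @param require_biallelic check ref/alt are two distinct single bases.
#' @param max_het_rate optional per-locus observed-heterozygosity cap
#'   (`NULL` = off; when enabled a conventional 0.80 is suggested).
#' @return list of class `filter_criteria`.
#' @export
filter_criteria <- function(maf_min = 0.05, missing_max = 0.30,
                            require_biallelic = TRUE, max_het_rate = NULL) {
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must be in [0, 0.5)")
  if (missing_max <= 0 || missing_max > 1) stop("missing_max must be in (0, 1]")
  if (!is.null(max_het_rate) && (max_het_rate < 0 || max_het_rate > 1)) {
    stop("max_het_rate must be in [0, 1]")
  }
  structure(list(maf_min = maf_min, missing_max = missing_max,
                 require_biallelic = require_biallelic,
                 max_het_rate = max_het_rate),
            class = "filter_criteria")
}

#' Filter SNP loci and report per-criterion removals
#'
#' @param gm a [geno_matrix()].
#' @param criteria a [filter_criteria()].
#' @return list with `genotypes` (filtered [geno_matrix()], locus order
#'   preserved) and `report` (data frame: criterion, n_removed, plus
#'   attributes `n_input` and `n_retained`).
#' @export
filter_snps <- function(gm, criteria = filter_criteria()) {
  stopifnot(inherits(gm, "geno_matrix"))
  n_input <- n_loci(gm)
  keep <- rep(TRUE, n_input)
  removed <- integer(0)

  if (criteria$require_biallelic) {
    bi <- nchar(gm$loci$ref) == 1 & nchar(gm$loci$alt) == 1 &
      gm$loci$ref != gm$loci$alt
    removed["not_biallelic"] <- sum(keep & !bi)
    keep <- keep & bi
  }

  maf <- suppressWarnings(compute_maf(gm))
  pass_maf <- !is.na(maf) & maf > criteria$maf_min
  removed["maf"] <- sum(keep & !pass_maf)
  keep <- keep & pass_maf

  miss <- colMeans(is.na(gm$calls))
  pass_miss <- miss < criteria$missing_max
  removed["missing"] <- sum(keep & !pass_miss)
  keep <- keep & pass_miss

  if (!is.null(criteria$max_het_rate)) {
    ho <- colSums(gm$calls == 1L, na.rm = TRUE) /
      pmax(colSums(!is.na(gm$calls)), 1L)
    pass_het <- ho <= criteria$max_het_rate
    removed["heterozygosity"] <- sum(keep & !pass_het)
    keep <- keep & pass_het
  }

  if (!any(keep)) warning("no loci retained by the filter")
  out <- gm[, which(keep)]
  report <- data.frame(criterion = names(removed), n_removed = unname(removed),
                       stringsAsFactors = FALSE)
  attr(report, "n_input") <- n_input
  attr(report, "n_retained") <- sum(keep)
  list(genotypes = out, report = report)
}
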