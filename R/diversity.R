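#' Polymorphic information content
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2` over marker allele
#' frequencies. For a biallelic SNP this is `1 - (p^2 + q^2) - 2 p^2 q^2`,
#' with maximum 0.375 at `p = q = 0.5`.
#'
#' @param p allele frequency vector summing to 1 (a single frequency is taken
#'   as biallelic `c(p, 1 - p)`).
#' @return PIC value.
#' @examples
#' pic(0.5)       # 0.375
#' pic(c(0.7, 0.3))
#' @export
pic <- function(p) {
  if (length(p) == 1) p <- c(p, 1 - p)
  if (abs(sum(p) - 1) > 1e-8) stop("allele frequencies must sum to 1")
  s2 <- sum(p^2)
  cross <- (s2^2 - sum(p^4)) / 2   # sum_{i<j} p_i^2 p_j^2
  1 - s2 - 2 * cross
}

#' Per-locus diversity statistics
#'
#' For each locus, over the non-missing calls of the chosen individuals:
#' `N` typed individuals; `Na` = number of alleles observed (frequency > 0);
#' `Ne = 1 / sum(p_i^2)` effective allele number; Shannon's
#' `I = -sum(p_i log p_i)` (with `0 log 0 = 0`); `Ho` = fraction of
#' heterozygous calls; `He = 1 - sum(p_i^2)`; `uHe = 2N/(2N - 1) * He`;
#' fixation index `F = (He - Ho)/He` (`NA` when `He = 0`); `MAF`; `PIC`.
#' Loci with fewer than two typed calls are returned as all-`NA` rows with a
#' warning.
#'
#' @param gm a [geno_matrix()].
#' @param individuals optional subset (labels or indices); default all.
#' @param group label recorded in the output (default `"Total"`).
#' @return data frame with one row per locus and columns `locus`, `group`,
#'   `N`, `Na`, `Ne`, `I`, `Ho`, `He`, `uHe`, `F`, `MAF`, `PIC`.
#' @export
locus_stats <- function(gm, individuals = NULL, group = "Total") {
  calls <- gm$calls
  if (!is.null(individuals)) calls <- calls[individuals, , drop = FALSE]
  n <- colSums(!is.na(calls))
  het <- colSums(calls == 1L, na.rm = TRUE)
  p <- colSums(calls, na.rm = TRUE) / (2 * n)
  q <- 1 - p
  low <- n < 2
  if (any(low)) {
    warning(sum(low), " locus/loci with fewer than 2 typed calls skipped")
    p[low] <- NA_real_; q[low] <- NA_real_
  }
  s2 <- p^2 + q^2
  plogp <- function(x) ifelse(x > 0, x * log(x), 0)
  out <- data.frame(
    locus = gm$loci$id,
    group = group,
    N = ifelse(low, NA_integer_, n),
    Na = (p > 0) + (q > 0),
    Ne = 1 / s2,
    I = -(plogp(p) + plogp(q)),
    Ho = ifelse(low, NA_real_, het / n),
    He = 1 - s2,
    uHe = (2 * n) / (2 * n - 1) * (1 - s2),
    stringsAsFactors = FALSE
  )
  out$F <- ifelse(out$He > 0, (out$He - out$Ho) / out$He, NA_real_)
  out$MAF <- pmin(p, q)
  out$PIC <- 1 - s2 - 2 * p^2 * q^2
  out
}

#' Summarise diversity statistics for one group
#'
#' Aggregates [locus_stats()] over loci: mean, standard error
#' (`sd / sqrt(L)`), min and max of each statistic, computed from per-locus
#' values (not from formulas applied to mean frequencies). Loci where `F` is
#' undefined (monomorphic within the group) are excluded from the `F`
#' aggregation, and the percentage of polymorphic loci (`Na >= 2`) within the
#' group is reported.
#'
#' @param gm a [geno_matrix()].
#' @param pm a [popmap()].
#' @param group a group label present in `pm`, or `"Total"` for all
#'   individuals (including unknown-type ones).
#' @return list of class `pop_summary` with elements `group`, `n_individuals`,
#'   `stats` (data frame: statistic, mean, se, min, max) and
#'   `percent_polymorphic`.
#' @export
population_summary <- function(gm, pm, group) {
  if (identical(group, "Total")) {
    members <- individuals(gm)
  } else {
    if (!group %in% pm$group) stop("unknown group label: ", group)
    members <- pm$individual[pm$group == group]
    members <- intersect(members, individuals(gm))
  }
  if (length(members) < 2) stop("group must have at least 2 genotyped members")
  ls <- locus_stats(gm, members, group)
  agg <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)),
      min = min(x), max = max(x))
  }
  stat_cols <- c("N", "Na", "Ne", "I", "Ho", "He", "uHe", "F", "MAF", "PIC")
  tab <- t(vapply(stat_cols, function(s) agg(ls[[s]]), numeric(4)))
  stats_df <- data.frame(statistic = stat_cols, tab, stringsAsFactors = FALSE,
                         row.names = NULL)
  structure(list(
    group = group,
    n_individuals = length(members),
    stats = stats_df,
    percent_polymorphic = 100 * mean(ls$Na >= 2, na.rm = TRUE)
  ), class = "pop_summary")
}

#' @export
print.pop_summary <- function(x, ...) {
  cat("Group", x$group, "(", x$n_individuals, "individuals ):",
      sprintf("%.2f%% polymorphic loci\n", x$percent_polymorphic))
  print(x$stats, digits = 4)
  invisible(x)
}

#' Diversity summary table across groups
#'
#' Runs [population_summary()] for every known group in the population map
#' and, optionally, for the total collection (all individuals including
#' unknown-type ones), returning a long-format table of means and standard
#' errors in the style of a per-subpopulation genetic-parameter table.
#'
#' @param gm a [geno_matrix()].
#' @param pm a [popmap()].
#' @param include_total add a `"Total"` block (default `TRUE`).
#' @return data frame with columns `group`, `n_individuals`,
#'   `percent_polymorphic`, `statistic`, `mean`, `se`, `min`, `max`.
#' @export
diversity_summary <- function(gm, pm, include_total = TRUE) {
  groups <- popmap_groups(pm)
  if (include_total) groups <- c(groups, "Total")
  do.call(rbind, lapply(groups, function(g) {
    s <- population_summary(gm, pm, g)
    cbind(group = g, n_individuals = s$n_individuals,
          percent_polymorphic = s$percent_polymorphic, s$stats)
  }))
}

#' Binned histogram counts of a per-locus statistic
#'
#' Convenience export used for MAF and PIC distribution tables.
#'
#' @param x numeric vector (e.g. a `MAF` or `PIC` column of [locus_stats()]).
#' @param breaks passed to [base::cut()]; default 10 equal bins over the range.
#' @return data frame with columns `bin` and `count`.
#' @export
binned_counts <- function(x, breaks = 10) {
  x <- x[!is.na(x)]
  b <- cut(x, breaks = breaks, include.lowest = TRUE)
  data.frame(bin = levels(b), count = as.integer(table(b)),
             stringsAsFactors = FALSE)
}
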