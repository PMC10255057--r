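#!/usr/bin/env Rscript
# Step 3 — per-locus and per-group diversity statistics.
#
# Computes Na, Ne, Shannon I, Ho, He, uHe, fixation index F, MAF and PIC per
# locus for the whole collection and per astringency-type group, plus the
# mean/SE/min/max summaries and the percentage of polymorphic loci per
# group, and binned MAF/PIC distributions.

library(gbspop)

gm <- read_vcf("results/filtered_calls.vcf")$genotypes
pm <- read_popmap("results/popmap.tsv", individuals = individuals(gm))

per_locus <- suppressWarnings(locus_stats(gm))
write.table(per_locus, "results/locus_stats_total.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

summ <- diversity_summary(gm, pm)
write.table(summ, "results/diversity_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

for (g in c(popmap_groups(pm), "Total")) {
  s <- population_summary(gm, pm, g)
  cat(sprintf("%-6s n=%2d  polymorphic %6.2f%%  mean F %+.3f  mean He %.3f\n",
              g, s$n_individuals, s$percent_polymorphic,
              s$stats$mean[s$stats$statistic == "F"],
              s$stats$mean[s$stats$statistic == "He"]))
}

write.table(binned_counts(per_locus$MAF, seq(0, 0.5, by = 0.05)),
            "results/maf_histogram.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(binned_counts(per_locus$PIC, seq(0, 0.375, length.out = 11)),
            "results/pic_histogram.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
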