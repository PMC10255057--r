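#!/usr/bin/env Rscript
# Step 1 — simulate the germplasm collection stand-in.
#
# The study collection (93 persimmon cultivars: 40 PCNA, 19 PCA, 23 PVNA,
# 9 PVA, 2 of unknown astringency type) was genotyped by GBS, but the read
# data were not deposited. This script generates a synthetic stand-in with
# the same design: four groups under weak Balding-Nichols differentiation,
# a mild heterozygote deficit, negative-binomial read depth and dropout
# missingness. Outputs: a VCF with allele depths, a population map, and a
# truth table of ancestral/group allele frequencies.

library(gbspop)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- sim_config(n_loci = 5000, n_unknown = 2, seed = 20230524)
sim <- simulate_dataset(cfg)
print(sim)

write_vcf(sim$genotypes, file.path(out_dir, "collection_truth.vcf"),
          depths = sim$depths)
write_popmap(sim$popmap, file.path(out_dir, "popmap.tsv"))

truth <- data.frame(locus = sim$genotypes$loci$id,
                    ancestral_p = sim$ancestral_p,
                    t(sim$group_freqs))
names(truth)[-(1:2)] <- paste0("freq_", cfg$group_names)
write.table(truth, file.path(out_dir, "truth_freqs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d individuals (%d typed) x %d loci; VCF, popmap and\ntruth table written under %s/\n",
            n_individuals(sim$genotypes), nrow(analyzable(sim$popmap)),
            n_loci(sim$genotypes), out_dir))
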