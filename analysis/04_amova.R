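#!/usr/bin/env Rscript
# Step 4 — AMOVA and pairwise Fst among astringency-type groups.
#
# Three-level AMOVA (among groups / among individuals within groups / within
# individuals) over the 91 typed individuals, with a 999-permutation test of
# Fst, and the pairwise-Fst matrix with per-pair permutation p-values.

library(gbspop)

gm <- read_vcf("results/filtered_calls.vcf")$genotypes
pm <- read_popmap("results/popmap.tsv", individuals = individuals(gm))

res <- amova(gm, pm, n_perm = 999, seed = 42)
print(res)
write.table(res$table, "results/amova_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pw <- pairwise_fst(gm, pm, n_perm = 999, seed = 42)
print(pw)
m <- pw$fst
m[upper.tri(m)] <- pw$p_value[upper.tri(m)]
write.table(cbind(group = rownames(m), as.data.frame(m)),
            "results/pairwise_fst.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
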