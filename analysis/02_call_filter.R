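#!/usr/bin/env Rscript
# Step 2 — genotype calling and SNP filtering.
#
# Calls genotypes from allele depths with the read-depth-fraction rules
# (homozygous when one allele holds >= 90% of reads, heterozygous at 40-60%,
# minimum depth 3; everything else missing), then filters loci to biallelic
# SNPs with MAF > 5% and missing rate < 30%. Writes the called matrix, the
# filter report and a per-chromosome SNP density table.

library(gbspop)

vcf <- read_vcf("results/collection_truth.vcf")
called <- call_matrix(vcf$depths)
cat("call classes:\n"); print(called$class_counts)

fl <- filter_snps(called$genotypes)
rep <- fl$report
cat(sprintf("loci: %d in -> %d retained\n",
            attr(rep, "n_input"), attr(rep, "n_retained")))
print(rep)

write_vcf(fl$genotypes, "results/filtered_calls.vcf")
write_geno_table(fl$genotypes, "results/filtered_calls.tsv")
write.table(cbind(rep, n_input = attr(rep, "n_input"),
                  n_retained = attr(rep, "n_retained")),
            "results/filter_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

dens <- as.data.frame(table(fl$genotypes$loci$chrom),
                      stringsAsFactors = FALSE)
names(dens) <- c("chrom", "n_snps")
write.table(dens, "results/snp_density_by_chromosome.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
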