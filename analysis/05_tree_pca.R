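#!/usr/bin/env Rscript
# Step 5 — Nei-distance neighbor-joining tree and genotype PCA.
#
# Builds the individual-level Nei genetic distance matrix over the whole
# collection (unknown-type cultivars included), the NJ tree with
# locus-bootstrap support, and the centered-dosage PCA.

library(gbspop)

gm <- read_vcf("results/filtered_calls.vcf")$genotypes

D <- nei_distance_matrix(gm)
write.table(cbind(individual = rownames(D), as.data.frame(round(D, 6))),
            "results/nei_distances.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

tr <- bootstrap_tree(gm, n_boot = 1000, seed = 42)
ape::write.tree(tr, "results/nj_tree.nwk")
sup <- suppressWarnings(as.numeric(tr$node.label))
cat(sprintf("NJ tree: %d tips; median bootstrap support %.0f%%\n",
            length(tr$tip.label), median(sup, na.rm = TRUE)))

pca <- snp_pca(gm, n_comp = 10)
print(pca)
write.table(cbind(individual = rownames(pca$scores),
                  as.data.frame(round(pca$scores, 5))),
            "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(component = seq_along(pca$explained),
                       explained = pca$explained),
            "results/pca_explained.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
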