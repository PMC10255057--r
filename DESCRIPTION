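Package: gbspop
Title: Population Genetic Analysis of GBS-Derived Biallelic SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population genetic analysis of codominant biallelic SNP
    genotypes such as those produced by genotyping-by-sequencing (GBS) of crop
    germplasm collections. Provides read-depth-fraction genotype calling,
    locus filtering (biallelicity, minor allele frequency, missingness),
    per-locus and per-population diversity statistics (Na, Ne, Shannon I, Ho,
    He, unbiased He, fixation index, PIC), three-level analysis of molecular
    variance (AMOVA) with permutation tests and pairwise Fst, Nei's genetic
    distance between individuals with neighbor-joining trees and locus
    bootstrap, genotype PCA, and Evanno delta-K selection of the number of
    admixture clusters. A Balding-Nichols simulator generates allele-depth
    datasets with controlled differentiation, inbreeding, depth noise and
    missingness for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
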