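---
title: "Population-genetic analysis of GBS SNP genotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genetic analysis of GBS SNP genotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbspop)
```

## Scope

`gbspop` analyzes codominant biallelic SNP genotypes of a structured
germplasm collection — the motivating case is a set of 93 persimmon
(*Diospyros kaki*) cultivars in four astringency-type groups (PCNA, PCA,
PVNA, PVA, sized 40/19/23/9, plus two cultivars of unknown type). The
pipeline enters at the allele-depth level: per-sample reference/alternate
read counts at candidate SNP sites. Everything upstream (library
preparation, demultiplexing, trimming, mapping, raw variant detection) is
out of scope, as is the admixture MCMC itself (only its delta-K
post-processing is implemented). Although the cultivars are hexaploid, the
genotypes are scored as diploid-style biallelic codominant calls — the
observation model of the original genotyping — and all statistics treat
each individual as contributing two alleles per locus.

## Genotype calling and filtering

A cell with `ref + alt = n` reads and alternate fraction `a = alt / n` is
called:

* missing if `n < 3` (the minimum-depth rule);
* homozygous alternate if `a >= 0.90`, homozygous reference if `a <= 0.10`
  (one allele holds at least 90% of reads);
* heterozygous if `0.40 <= a <= 0.60`;
* otherwise missing. Fractions in `[0.2, 0.4)` and `(0.6, 0.9)` form the
  classical "other" class of depth-fraction callers; the residual band
  `(0.1, 0.2)` is unclassified by those rules. Both are treated as missing
  data downstream — diversity statistics are computed on called genotypes
  only — but `call_matrix()` tallies them separately, since the "other"
  rate is a useful diagnostic of depth and ploidy artefacts.

All thresholds are exposed in `call_thresholds()`. Comparisons carry an
epsilon of 1e-9 because read fractions are ratios of small integers
(`2/20` must count as exactly 0.10).

Locus filtering (`filter_snps()`) retains biallelic loci with minor allele
frequency strictly above 0.05 and missing-call fraction strictly below
0.30, in that order; removals are reported per criterion so the report
reconciles exactly (`input = removed + retained`). An optional
observed-heterozygosity cap (`max_het_rate`, off by default, 0.80 when
enabled) supports the common practice of discarding loci whose excess
heterozygosity suggests collapsed paralogs; no principled universal value
exists, which is why it is off by default. Filtering is idempotent and
monotone in the MAF threshold, and both properties are tested.

## Diversity statistics

For each locus and individual subset, with allele frequencies `p, q`
estimated from dosages over the `N` typed individuals:

* `Na`: alleles observed; `Ne = 1 / (p^2 + q^2)`;
* Shannon `I = -(p log p + q log q)` with the convention `0 log 0 = 0`;
* `Ho`: fraction of heterozygous calls; `He = 1 - (p^2 + q^2)`;
* `uHe = 2N / (2N - 1) * He`; `F = (He - Ho) / He`, undefined at
  monomorphic loci;
* `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`, maximum 0.375 for a
  biallelic marker.

Missingness enters only through the per-locus `N`; nothing is imputed.
Group summaries average per-locus values (never formulas applied to mean
frequencies), exclude undefined `F` values from the `F` mean rather than
zero-filling them — which is why the summary `F` does not equal
`(mean He - mean Ho) / mean He` — and report the percentage of loci
polymorphic within the group. The identities `He = 1 - 1/Ne` and
`uHe/He = 2N/(2N-1)` hold per locus to machine precision and are asserted
in the test suite. The "Total" summary uses all individuals including
unknown-typed ones; group-wise analyses use only typed individuals.

## AMOVA and fixation indices

The three-level AMOVA treats each typed individual as two allelic
observations per locus (dosage `d` -> indicator alleles summing to `d`)
and partitions squared deviations into among-groups, among-individuals
within groups, and within-individuals strata. Per locus, with group
dosage sums `S_g`, typed counts `n_g`, totals `T` and `N`:

* `SS_total = T - T^2 / (2N)`;
* `SS_among_groups = sum_g S_g^2 / (2 n_g) - T^2 / (2N)`;
* `SS_within_individuals = het_count / 2`;
* `SS_among_individuals` by subtraction.

Variance components are solved per locus from the expected mean squares —
`E[MS_within] = Vc`, `E[MS_among_ind] = Vc + 2 Vb`,
`E[MS_among_groups] = Vc + 2 Vb + n0 Va` with the unequal-size coefficient
`n0 = (2N - sum_g (2 n_g)^2 / (2N)) / (G - 1)` — and summed over loci, so
loci with missing calls contribute with their own counts (a locus
informative in fewer than two groups, or with no within-group replication,
is skipped). The reported degrees of freedom describe the analyzed design
(`G - 1`, `N - G`, `N`, total `2N - 1`); with complete data the per-locus
and pooled routes coincide exactly, which the pairwise-distance oracle test
verifies on random small instances.

Negative variance components — expected under weak differentiation — are
floored at zero for percentages and indices by default (`truncate_negative`,
with a message when it triggers); the untruncated components are always
returned. `Fst = Va / (Va + Vb + Vc)`, `Fis = Vb / (Vb + Vc)`,
`Fit = (Va + Vb) / (Va + Vb + Vc)`.

The permutation test reassigns whole individuals to groups (sizes
preserved), recomputes Fst, and reports
`p = (1 + #{Fst_perm >= Fst_obs}) / (1 + n_perm)`; 999 permutations give
the conventional p-value floor of 0.001. The permutation stream is seeded
and applied in a canonical individual ordering, so the p-value is
reproducible and invariant to row order. Pairwise Fst runs the same
machinery on each pair of groups.

## Distances, trees, PCA, delta-K

Nei's standard genetic distance is computed between individuals (the
collection is clustered at cultivar level): each dosage becomes a
within-individual allele-frequency vector (`0 -> (1,0)`, `1 -> (0.5,0.5)`,
`2 -> (0,1)`), and over loci typed in both individuals
`D = -log(Jxy / sqrt(Jx Jy))`. Missing loci are handled by
pairwise-complete deletion; a pair sharing no typed locus is an error. A
zero identity is clamped at `-log(1e-12)` (about 27.6) to keep the matrix
finite.

Neighbor joining is delegated to `ape::nj()` behind `nj_tree()`, which
additionally clamps negative branch lengths to zero, transferring the
deficit to the sibling branch — the standard remedy for the small negative
estimates NJ produces on non-additive inputs. Bootstrap support resamples
loci with replacement, rebuilds distance and tree per replicate, and maps
bipartition frequencies onto the full-data tree with `ape::prop.clades`
(unrooted comparison). On additive inputs NJ recovery is exact; the test
suite checks ≤8-taxon additive matrices against an exhaustive topology
search (every unrooted topology fit by least squares).

PCA mean-imputes missing dosages per locus, centers columns, and by
default does not rescale (centered dosages); `sqrt(p(1-p))` scaling is
available by flag since conventions differ between tools and neither is
canonical for this analysis. Scores come from the SVD of the centered
matrix; explained-variance fractions are normalised squared singular
values.

Delta-K consumes a table of replicate admixture log-likelihoods over a
contiguous K range (at least three K values, at least two replicates
each): `L'(K)` is the successive difference of replicate means,
`|L''(K)|` its absolute second difference, and
`deltaK = |L''(K)| / sd(L(K))`, defined only for interior K and flagged
undefined where the replicate standard deviation is zero.

## The synthetic collection

No genotype data were deposited for the motivating collection, so the
package ships a generator whose defaults emulate the study conditions:

| parameter | default | rationale |
|---|---|---|
| group sizes | 40/19/23/9 (+2 unknown optional) | the collection's design |
| `fst` | 0.05 | within the observed pairwise band 0.016–0.094 |
| `inbreeding_f` | 0.10 | observed mean fixation index ~0.09–0.17 |
| `n_loci` | 2000 | 10^3–10^4 regime at desk scale |
| ancestral MAF | Uniform(0.05, 0.5) | most loci survive the MAF filter |
| `mean_depth` / dispersion | 25 / 4 (negative binomial) | reproduces the observed post-filter typed-sample mean of ~79 of 93 |
| `base_error` | 0.01 | typical short-read miscall rate |
| `missing_rate` | 0.05 | dropout on top of depth-driven missingness |

Group allele frequencies follow the Balding–Nichols model (Beta around the
ancestral frequency with variance `Fst p (1 - p)`) — the standard
Fst-parameterised choice when no demographic history is specified.
Genotypes follow the inbreeding-adjusted Hardy–Weinberg law; depths are
negative binomial (GBS coverage is overdispersed; `Inf` dispersion gives
the Poisson limit); alternate reads are binomial with mean `base_error`,
0.5 or `1 - base_error` by true dosage. Loci are independent: no linkage
disequilibrium, no coalescent ancestry, and no hexaploid dosage — passing
tests therefore demonstrate estimator correctness under this observation
model, not robustness to LD, allele-dosage ambiguity or non-equilibrium
demography in real data. One visible consequence of the calling rules is
worth noting: because the "other" class preferentially removes
heterozygous cells at moderate depth, fixation indices estimated from
called data sit above the generative `inbreeding_f`; estimator-recovery
checks therefore run on the true simulated genotypes.

## Validation at a glance

The test suite ties the implementation to analytic worked values (PIC and
diversity maxima at `p = 0.5`, the `uHe` correction at `N = 66`, the
3/87/91 AMOVA layout for 91 individuals in 4 groups, the NJ three-point
formula), to independent oracles (pairwise-distance AMOVA sums of squares,
exhaustive NJ topology search, dense eigendecomposition for PCA), and to
statistical calibration: AMOVA recovers generative `fst` of 0.02/0.05/0.10
within ±0.03 (2000 loci, the collection's group sizes, 5 seeds each),
total-population mean `F` recovers `inbreeding_f = 0.1` within ±0.03 at
`fst = 0` (isolating inbreeding from the Wahlund effect), and the Fst
permutation test rejects a true null in 2–8% of 200 runs at the 5% level
(199 permutations, 300 loci per run — sizes chosen to keep the default
suite under a minute of AMOVA work while leaving Monte-Carlo error well
inside the bands).

## Known limitations

* Diploid-coded calls only; allele dosage in polyploids is not modelled.
* The AMOVA hierarchy is fixed at three levels (group / individual /
  allele); regional strata above groups are not supported.
* Nei distances between individuals with very little shared typing are
  noisy; the generator's missingness is benign here, but real GBS data may
  need a shared-loci floor before tree building.
* `read_vcf` handles GT/AD biallelic records only; multiallelic records
  are dropped (with a count), not decomposed.
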