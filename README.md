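# endopoe

Parent-of-origin effects of RNA polymerase IV on *Arabidopsis* endosperm
expression.

Endosperm is the triploid seed tissue (2 maternal : 1 paternal genomes)
that mediates maternal resource transfer to the embryo. RNA Pol IV
initiates the biogenesis of 24-nt siRNAs that direct DNA methylation
(RdDM), and its loss in the mother versus the father perturbs the
endosperm differently — at some genes in *opposite* directions. `endopoe`
implements the full analysis used to dissect such effects from
reciprocal-cross sequencing data, plus a synthetic-data generator with
known ground truth so every stage can be validated by parameter recovery:

* **Allele-specific quantification.** A SNP-substitution pseudogenome
  separates maternal (Ler-like) from paternal (Col-0-like) reads; per-read
  SNP votes assign each read to an allele, and per-feature tallies give
  `percent maternal = 100·m/(m+p)` with a testability floor of 10
  informative reads.
* **sRNA analysis.** PCR-duplicate collapse, 21–24-nt size binning,
  sliding-window (300 bp) and gene/TE counting, and cluster calling with
  dicer size range 20–25 nt, a 0.5-rpm coverage floor and
  predominant-size classification.
* **Differential abundance.** A negative-binomial Wald engine with
  *reference-feature* median-of-ratios size factors: when most TE loci
  lose their sRNAs in the mutant, library size is estimated from genic +
  miRNA loci only, so genuine losses are not normalized away. Per-feature
  method-of-moments dispersion; the Wald statistic is referred to a t
  distribution with `n_A + n_B − 2` df so type-I error stays near nominal
  at 2–3 replicates. Calls require |log2FC| ≥ 1, BH-adjusted p ≤ 0.05 and
  a reference-condition normalized mean ≥ 5.
* **Methylome analysis.** Strand-aware CG/CHG/CHH context assignment,
  chloroplast bisulfite-conversion QC (≥ 98%), 300-bp/100-bp-step window
  methylation with ≥ 3 common informative cytosines at mean depth ≥ 6,
  a triploid dosage filter (maternal DNA read fraction within 67 ± 15%),
  within-genotype replicate-variability masking, and DMR calling at
  context thresholds of 10% (CHH), 20% (CHG), 30% (CG) with merging of
  overlapping same-direction windows.
* **Imprinting.** Allelic-bias classes (maternally biased > 80%,
  paternally biased < 20%, biallelic in between, inclusive), imprinted
  sRNA region (ISR) summaries as median window counts per genotype, and
  exact hypergeometric enrichment.
* **Antagonism.** Partition of misregulated genes across the
  mat-heterozygote / pat-heterozygote / null contrasts,
  an exact test for opposite-direction misregulation, the additive
  parental-effect prediction `log2FC(null) = log2FC(mat) + log2FC(pat)`,
  and the inverse maternal/paternal regression slope.
* **Integration.** 1-kb proximity tallies, the relative-distance
  statistic (uniform at 0.02 per 1%-bin under spatial independence), and
  per-nucleotide 5′-end (NanoPARE-style) differential sites classified as
  TSS-proximal versus internal (putative cleavage).

## Worked example

Simulate a desk-scale endosperm experiment (two 200-kb contigs plus a
150-kb chloroplast, 400 genes, 200 TEs, 30 + 30 imprinted sRNA regions,
100k sRNA reads per library, 30× methylomes) and run the main analyses:

```r
library(endopoe)

cfg <- sim_config(seed = 7)
sim <- simulate_genome_and_snps(cfg)

## mRNA differential expression in the three contrasts
mrna <- simulate_mrna_counts(sim, n_reps = 3)
res_mat  <- diffex(mrna$total, c("WT", "mat_het"))
res_pat  <- diffex(mrna$total, c("WT", "pat_het"))
res_null <- diffex(mrna$total, c("WT", "null"))

opp <- opposite_direction_test(res_mat, res_pat)
cat(sprintf("shared genes: %d, opposite direction: %d (p = %.2e)\n",
            opp$n_shared, opp$n_opposite, opp$p_value))
#> shared genes: 68, opposite direction: 47 (p = 1.37e-03)

parts <- partition_sets(res_mat, res_pat, res_null)
mat_not_null <- subset(parts, call_mat %in% c("up", "down") &
                              !(call_null %in% c("up", "down")))
fit <- inverse_slope(mat_not_null$log2fc_mat, mat_not_null$log2fc_pat)
cat(sprintf("slope (mat-only genes): %.2f (R2 = %.2f, n = %d)\n",
            fit$slope, fit$r_squared, fit$n))
#> slope (mat-only genes): -0.88 (R2 = 0.87, n = 61)

pred <- additive_prediction(res_mat, res_pat, res_null)
mean(pred$discrepancy, na.rm = TRUE)
#> [1] -0.019
```

Most genes misregulated in both heterozygotes move in opposite
directions, and for genes called only in the maternal heterozygote the
paternal effect runs against the maternal one (negative slope): the
generator plants antagonistic gene pairs with `β_pat = −β_mat`, and the
pipeline recovers them. The additive prediction is unbiased because the
null genotype's mean is exactly the sum of the two parental effects on
the log2 scale.

```r
## allele-specific sRNAs over genes and TEs in wild type
srna <- deduplicate(simulate_srna_reads(sim, "WT", 1))
ac <- allelic_feature_counts(srna, sim$features, sim$snps, sim$genome)
table(classify_bias(ac)$class)
#>         biallelic maternally_biased paternally_biased        untestable
#>               223                45                20               393

## methylome: conversion QC and CHH DMRs, mat_het vs WT
meth_wt <- rbind(simulate_methylome(sim, "WT", 1),
                 simulate_methylome(sim, "WT", 2))
meth_mh <- rbind(simulate_methylome(sim, "mat_het", 1),
                 simulate_methylome(sim, "mat_het", 2))
conversion_qc(meth_wt, "chrC", min_depth = 10)$conversion_rate
#> [1] 99.00

jt  <- methyl_join(meth_wt, meth_mh)
win <- window_methylation(jt, sim$genome)
dmrs <- call_dmrs(win, jt)
table(dmrs$context, dmrs$direction)
#>       hypo
#>   CHH   29
```

The 29 hypo-CHH DMRs are the generator's 30 maternal-memory RdDM
targets, which lose CHH methylation when the mutation is maternally
inherited; CG and CHG backgrounds stay below their thresholds. The
untestable sRNA features are those with fewer than 10 allele-informative
reads (mostly short or weakly expressed loci), and the maternal bias
classes reflect the planted imprinted sRNA regions.

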