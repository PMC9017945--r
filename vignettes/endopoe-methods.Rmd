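---
title: "Methods: allele-specific endosperm genomics with endopoe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific endosperm genomics with endopoe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endopoe)
```

## The biological setting

Endosperm is triploid: two maternal genomes from the central cell and one
paternal genome from a sperm cell. Two consequences anchor everything in
this package. First, any DNA-derived read pool should be two-thirds
maternal in expectation, and for most genes about two-thirds of
transcripts come from maternal alleles; departures from that baseline are
either biology (imprinting) or artifact (allele-specific coverage loss),
and the pipeline must distinguish the two. Second, effects of a mutation
can enter through the mother, through the father, or through the zygote
itself, and a reciprocal-heterozygote design (mutant mother x wild-type
father, and the reverse) separates the parental components.

RNA Pol IV initiates the production of 24-nt siRNAs that direct DNA
methylation at transposons and some genes. In endosperm, loss of maternal
versus paternal Pol IV perturbs partly disjoint sets of sRNA loci,
methylated regions, and genes — and at a subset of genes the two parental
effects run in *opposite* directions, which is the headline inference the
`antagonism` functions formalize.

## Coordinate and data model

Internally everything lives on 1-based, closed-interval coordinates in
`GRanges` — the Bioconductor convention — with a single rule: conversions
happen only at I/O boundaries. BED and bedGraph (0-based half-open) are
shifted on read and write; GFF3 and VCF (1-based) pass through. Keeping
one internal convention, whichever it is, is what eliminates off-by-one
bugs; adopting the convention of the host ecosystem means `findOverlaps`,
`reduce` and `distanceToNearest` can be used directly.

Reads use a documented six-column SAM-like TSV (id, contig, 0-based
leftmost start, strand, sequence as sequenced, number of equally good
hits). The 5' end of a minus-strand read is its rightmost coordinate; all
counting uses 5'-end containment so that a read lands in exactly one
feature (ties to the earlier coordinate-sorted feature) and totals are
conserved across overlapping annotations.

## Allele assignment

The maternal genome is the reference with every SNP substituted
(a pseudogenome); because only substitutions are allowed, both parental
genomes share one coordinate frame and "liftover" is the identity.
A read votes at every SNP it overlaps; unanimous votes assign the read,
anything else — no SNP, a non-parental base, or a conflict — is
`ambiguous`. Conflicted reads are retained as ambiguous rather than
dropped with an error: sequencing errors at SNPs would otherwise bias
allelic ratios. Multimapped reads are excluded from allelic tallies
(their placement, hence their SNP overlap, is unreliable) but still count
in non-allelic totals. Features need at least 10 allele-informative reads
to be testable, and `percent maternal` is computed on informative reads
only.

## Differential abundance

The engine is a two-group negative-binomial Wald test with one deliberate
twist: **reference-feature size factors**. Standard median-of-ratios
normalization assumes most features do not change. When Pol IV loss
abolishes sRNAs at the majority of TEs, that assumption fails and the
wild-type library size is underestimated, hiding true losses. The
pipeline therefore computes median-of-ratios over a caller-chosen
reference set — genic plus miRNA loci, which include Pol IV-independent
loci — and TEs are tested against that scale. Passing all features
reproduces the textbook estimator exactly.

Per feature, dispersion is method-of-moments on normalized counts pooled
within groups (floored at 1e-8); the log2 fold change uses a 0.5
pseudocount for display; the Wald statistic divides the fold change by a
delta-method standard error with the NB variance evaluated at the
estimated group means (the pseudocount appears only in the log
denominator, so a group with zero counts keeps a finite, conservative
variance contribution).

One calibration choice deserves emphasis. With 2-3 replicates per group,
the per-feature variance estimate carries only `n_A + n_B - 2` degrees of
freedom, and a standard-normal reference for the Wald statistic rejects
true nulls at roughly twice to three times the nominal rate. The
statistic is therefore referred to a t distribution with
`n_A + n_B - 2` df. At the simulated study conditions (3 vs 3, mean 100,
dispersion 0.05) this keeps the type-I error within Monte-Carlo error of
5% while detecting planted 4-fold effects with more than 90% power.
Dispersion shrinkage across features (as mature DE tools do) is
deliberately omitted — it is unnecessary at simulated depths — and is the
main known deviation from those tools; the cost is power on borderline
effects at two replicates per group.

Calls require all three of: |log2FC| >= 1 (a 2-fold change), BH-adjusted
p <= 0.05, and a reference-condition normalized mean of at least 5
(weakly expressed features are `untested`, not `ns`).

## sRNA processing and cluster calling

Duplicates are collapsed by full sequence identity (library adapters
carry random terminal bases, so identical full sequences are PCR
copies). Sizes 21-24 nt are binned; fraction plots use all aligned reads
as the denominator by default. Window counting supports both dialects in
use — 300-bp windows with 20-bp overlap (general counting) and with
200-bp overlap (the imprinted-region analysis) — and two counting modes:
`overlap` (a read counts in every covering window, matching
interval-intersection tools, the default) and `assign` (one window per
read, conserving totals).

Cluster calling merges read 5'-start positions into islands, merges
islands closer than `pad = 75` bp, and keeps clusters at or above
`mincov = 0.5` reads per million. A cluster's predominant size is the
modal length within the dicer range 20-25 nt, reported only when the
dicer fraction is at least 0.8 and the mode is a strict plurality; ties
and sub-threshold dicer fractions give the explicit `none` class. The
`pad` and 0.8 values follow the defaults of the established cluster
caller in this field, since only `dicermin`, `dicermax` and `mincov` are
prescribed; all are arguments. Multimapped reads are dropped by default;
the optional weighted mode gives a multimapper weight `1/n_hits` when at
least one unique-read 5' start lies within `pad` of its own, emulating
unique-guided weighting.

## Methylome analysis

Cytosine context is assigned from the strand-appropriate trinucleotide
(CG, CHG, CHH with H = A/C/T, read 5'-to-3' on the cytosine's strand);
cytosines within 2 bp of a contig end are dropped. The chloroplast is
unmethylated, so apparent methylation there estimates bisulfite
conversion failure: the QC statistic is computed over chloroplast
cytosines with at least 10 reads and libraries below 98% conversion are
flagged.

Windowed comparison uses 300-bp windows at 100-bp steps. Only cytosines
covered in *both* conditions count ("common informative"); a window needs
at least 3 of them and a mean depth of at least 6 reads per cytosine in
each condition. The depth rule is read as a mean over the window's common
informative cytosines — a strict per-cytosine rule would discard most
windows at 30x pooled coverage — with `strict_depth = TRUE` available.
Two further filters precede DMR calling: windows whose maternal DNA read
fraction falls outside 67 +/- 15% (inclusive, i.e. [52, 82]) are removed,
because under- or over-representation of one parental genome makes the
pooled methylation estimate untrustworthy in triploid tissue; and windows
already differing between replicates of the same genotype by a DMR-sized
margin are masked. The dosage filter is applied per window (whether the
original procedure filtered windows or larger regions is ambiguous; the
window reading is the conservative one).

DMRs require a between-genotype difference of at least 10 (CHH), 20
(CHG) or 30 (CG) percentage points. Overlapping qualifying windows of the
same context *and direction* merge into one region (the 100-bp step
guarantees adjacency implies overlap; mixed directions never merge), and
the merged region's methylation is recomputed from its cytosines, not
averaged over windows. CHG DMRs are computed but are rare at these
thresholds and carry no downstream integration by default.

## Imprinting and antagonism

Allelic bias classes put maternally biased loci above 80% maternal,
paternally biased below 20%, and biallelic in the closed interval
[20, 80] — the boundary values belong to biallelic, and both bounds are
arguments. ISR summaries locate the 300/100 windows overlapping each
imprinted sRNA region and report the median normalized count per
genotype (R's midpoint rule for even counts), the robust per-region
statistic used to display parental-memory behavior.

The antagonism analysis takes the three classified contrasts on a shared
gene universe. Genes called in both heterozygote contrasts are "shared";
a shared gene whose fold-change estimates disagree in sign "changed in
the opposite direction" (direction uses the estimated sign once a gene is
called in each contrast — the 2-fold threshold applies to calling, not to
the sign). Enrichment of opposite-direction genes is evaluated exactly on
the shared-set composition: conditional on the number of up-calls in each
contrast, the count of concordant up/up genes is hypergeometric under
independence, and an excess of opposite pairs is its lower tail. The
additive model predicts the null genotype's fold change as the sum of
the two parental log2 fold changes; the per-gene discrepancy
(observed - predicted) is reported, and under the generator's exact
additivity its mean shrinks to sampling error as replication grows.
The inverse relationship is summarized by ordinary least squares of the
paternal on the maternal fold change (the regression method in the
original analysis is unnamed; OLS is the transparent default).

## Per-nucleotide 5'-end analysis

5'-end capture reads map both transcription start sites and internal
cleavage products. Sites are tested one nucleotide at a time with the NB
engine (no fold floor, adjusted p <= 0.05) using total-count size factors
(per-nucleotide tracks are too sparse for median-of-ratios). Significant
sites within 50 nt of a gene's annotated, strand-aware 5' end are
TSS-proximal; other in-gene sites are internal (putative cleavage). The
50-nt window is a package choice (no value is prescribed) and is an
argument. A gene whose expression rises purely transcriptionally shows
up-regulated TSS-proximal sites and no internal losses — the signature
that distinguishes transcription from relieved cleavage.

## Spatial association

`proximity_1kb` reports the fraction of genes within 1 kb (edge-to-edge,
0 when overlapping) of any region in a set. `relative_distance` is the
scale-free complement: each query midpoint is placed between its two
flanking reference midpoints and scored as
`min(m - b1, b2 - m) / (b2 - b1)` in [0, 0.5]; under spatial independence
the statistic is uniform, so each 0.01-wide bin holds frequency 0.02,
and spatial attraction piles mass into the low bins. Midpoints are the
integer floor of `(start + end) / 2`; query midpoints outside the span of
the reference midpoints are skipped and counted. The matched-baseline
generator redraws interval sets with identical counts and lengths,
uniformly placed, five replicates by default.

## The synthetic data: what it emulates, and what it does not

The generator fixes a complete latent state (`GroundTruth`) and derives
every dataset from it:

* **Genome and SNPs.** Two 200-kb uniform-random nuclear contigs plus a
  150-kb chloroplast; SNPs at rate 1/150 bp (Col/Ler-like density),
  never adjacent, never on the chloroplast; the reference is the
  paternal genome and alternate alleles are maternal.
* **Panels.** 400 genes, 200 TEs, 20 miRNA loci, 30 maternal-memory and
  30 paternal-memory imprinted sRNA regions, placed without overlap
  within each class.
* **sRNA libraries.** 100k reads; per-locus NB counts (dispersion 0.1)
  split into maternal/paternal components (biallelic bias 2/3, imprinted
  biases 0.95/0.05); 24-nt-predominant sizes (21-nt for miRNA loci); a
  5% Pol IV-independent uniform background at genome dosage. Genotype
  rules encode parental memory: Pol IV-dependent loci emit only
  background in the null; a maternal-memory locus emits maternal reads
  only when the mother is wild type; paternal-memory loci mirror that;
  miRNA loci ignore genotype.
* **mRNA counts.** Log2 mean `beta0 + beta_mat*I(mother mutant) +
  beta_pat*I(father mutant)` with NB noise (dispersion 0.05), so the
  null genotype is *exactly* additive in the noiseless means. Panels:
  60 antagonistic genes with `beta_pat = -beta_mat` (the antagonism
  ratio is configurable), 80 maternal-effect, 30 paternal-effect, 30
  same-direction genes, |beta| in 1.5-3 log2 units (effect-size
  distributions are a calibration choice, not an empirical claim).
  Allelic splits are beta-binomial around 2/3, or 0.95/0.05 for the 40
  MEGs and 20 PEGs.
* **Methylomes.** Every genomic cytosine at 30x with maternal:paternal
  depth 2:1; background methylation 20% CG / 8% CHG / 3% CHH; RdDM
  targets (TEs and memory regions) at 30% CHH collapsing to 5% when the
  controlling parent's Pol IV was absent — a planted delta of 25 points
  against the 10-point CHH threshold; unmethylated cytosines read as
  methylated with probability 1% (conversion 0.99); 40% of reads are
  allele-assignable.
* **5'-end tracks.** A TSS spike per gene scaled to its mRNA mean, an
  internal cleavage spike at designated genes present only while the
  sRNA machinery is active, and a fixed noise-site panel shared across
  genotypes.

Each library draws from its own stream, derived from the master seed and
the (assay, genotype, replicate) labels by a stable hash — adding a
library never perturbs existing ones, and a fixed seed reproduces every
byte.

What the generator does **not** emulate: sequencing error, mappability
and GC biases, adapter artifacts, seed-coat contamination, genome-wide
linkage between assays (methylation and expression are conditionally
independent given the truth), and realistic genome structure (no introns,
no repeat families, uniform base composition). Passing tests therefore
demonstrate that the *algorithms* recover planted truth under the stated
statistical model — not that the model captures every failure mode of
real libraries.

One desk-scale caveat is worth recording. At 100k reads over a 400-kb
nuclear genome, the uniform background alone puts ~5 reads in a 500-bp
locus, which is comparable to a coverage floor equivalent to 0.5 rpm at
real sequencing depth. "Cluster absence in the null" is therefore
asserted as strong per-locus depletion (>= 90% coverage loss at >= 95% of
Pol IV-dependent loci) rather than literal zero overlap — at full scale
the background per locus is far below the floor and the two formulations
coincide.

## Numerical choices and degenerate inputs

* All rates/probabilities are validated into [0, 1]; counts must be
  non-negative; genotype labels come from the closed set
  `WT, mat_het, pat_het, null`.
* Features with all-zero counts in both groups are `untested` (p is
  `NA`), excluded from BH correction, and re-inserted as `NA`.
* Dispersion floor 1e-8; size factors are rescaled to geometric mean 1;
  a reference set with no feature positive in every sample is an error
  (the estimator would be undefined), with advice to enlarge the set.
* Predominant-size ties and dicer fractions below 0.8 give `none`; the
  rpm floor is inclusive (a cluster at exactly 0.5 rpm is kept).
* Window tiling emits full-width windows only; in `assign` mode, 5'
  coordinates past the last window fall back to the last window so the
  library total is conserved.
* The empty SNP table makes the pseudogenome the identity; an empty
  region set makes `proximity_1kb` return fraction 0 with a warning; a
  reference set with fewer than two intervals per contig is an error for
  `relative_distance`.
* Exact boundary values are kept inclusive throughout: percent maternal
  20 and 80 are biallelic, dosage 52 and 82 are retained, methylation
  deltas exactly at threshold are DMR windows.

## Problem sizes used by the test suite

Unit tests run on a reduced configuration (two 50-kb contigs, 60 genes,
20k-read libraries); end-to-end recovery checks and the acceptance
script use the default configuration above. The full suite completes in
under a minute on a single CPU; the acceptance script in a few seconds.

## Known limitations

* No dispersion shrinkage: power at 2 replicates per group is limited to
  large effects; the t reference is conservative for clear-cut
  present/absent features.
* No multi-factor designs or covariates; contrasts are two-group.
* Per-allele DMR calling is out of scope — the dosage filter guards the
  pooled estimate instead, as in the original design.
* The Col-0 introgression exclusion list for the Ler mutant line is an
  input, not computed.
* Allele assignment compares full reads; the original aligner ignored
  4 nt at each read end, which full-read comparison slightly
  over-informs on error-free synthetic reads (no effect here; real data
  would need end-trimming first).
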