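---
title: "Single-pollen transcriptome and methylome analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-pollen transcriptome and methylome analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollensc)
```

## The scientific problem

In maize, a set of pollen-expressed genes carries transposable-element-like
DNA methylation (teM: high CG *and* high CHG methylation in the coding
sequence) in the plant body, where they are silent. Two DNA glycosylases,
MDR1 and DNG102, actively demethylate such loci in the pollen vegetative
cell, and at least one functional copy is required for pollen viability.
Because a double homozygous mutant plant cannot be made, the natural
experiment is the segregating pollen of a double heterozygote: each haploid
grain carries one of four genotypes in expected 1:1:1:1 ratio, and
single-grain mRNA sequencing lets the double-mutant transcriptome be
compared with its wild-type and single-mutant siblings from the same tassel.

`pollensc` implements that analysis as a reusable pipeline: CEL-seq ingest
and UMI counting, SNP-based haploid genotyping, library-complexity QC,
correlation clustering, negative-binomial Wald differential expression with
Holm correction, methylome epiallele classification and methylated pollen
gene (MPG) selection, absolute-abundance timecourse normalization, and
pollen-area bimodality analysis. A synthetic-data generator reproduces the
statistical structure of the experiment with ground-truth labels, so every
stage has recovery tests.

## Ingest model

Read 2 of a CEL-seq library is, positionally, a 10-nt unique molecular
identifier (UMI), a 6-nt sample barcode, then poly-T; read 1 carries the
transcript sequence. The pipeline:

* demultiplexes by **exact** barcode match (one mismatch discards the read);
* counts, per gene and sample, the number of **distinct** UMI sequences.

UMI deduplication is exact-match and scoped per gene: no edit-distance
(directional network) collapsing is attempted. At 4^10 UMI space and
per-gene molecule counts in the hundreds, collision effects are far below
the biological noise floor, and the generator lets tests verify exact
recovery of true molecule counts. Gene assignment of read 1 is an input
(from an upstream mapper or the generator); alignment is out of scope.

## Haploid genotyping

The two mutations cannot be genotyped directly (too little coverage), so
the pipeline uses *sentinel genes*: three expressed genes on each flank of
each locus whose SNPs distinguish the mutant-linked from the wild-type-linked
haplotype. Rules:

* **Per sentinel** (`call_sentinel_allele`): an allele is called when total
  spanning reads ≥ `min_reads` (default 2) and the majority fraction is ≥
  `majority` (default 0.8); otherwise the sentinel is ambiguous. Biallelic
  evidence therefore falls into ambiguity rather than error. The original
  calls were made by eye in a genome browser; the thresholds here are the
  algorithmic substitute and are configurable.
* **Per locus** (`genotype_grain`): each flank must contribute at least one
  informative sentinel and *all* informative sentinels on both flanks must
  agree. A single discordant informative sentinel — the signature of
  recombination between the sentinel and the locus — forces the locus to
  ambiguous. This is the conservative reading of requiring consistency on
  both sides: a recombinant grain is never mis-called.
* **Per grain**: `double` iff both loci are mutant; ambiguous if either
  locus is.

Segregation of the four classes is tested with the Pearson chi-squared
goodness-of-fit statistic against 1:1:1:1 (`segregation_chi2`); on the
observed counts (4, 7, 6, 6) this gives p = 0.843.

## QC and clustering

Single-grain libraries split into two depth populations (intact grains
around 5.5e5 UMIs; incompletely lysed grains around 5.4e3).
`filter_low_complexity` fits a two-component Gaussian mixture to log10
total UMIs and drops the low component, guarded by a minimum mean gap
(default 0.8 log10 units ≈ 6-fold) so that unimodal depth distributions
exclude nothing. A fixed threshold can be supplied instead.

`flag_anomalous` marks (i) samples whose mean off-diagonal Pearson
correlation is more than 3 SD below the mean of the *other* samples'
statistic — the leave-one-out form is used because a single strong outlier
inflates the pooled SD enough to mask itself at these sample sizes — and
(ii) grains with biallelic sentinel expression (≥ 2 sentinels on one flank
failing the majority rule with reads on both alleles), the signature of a
doublet or contaminated well.

`correlate_and_cluster` filters genes to mean raw TPM ≥ 500 (the mean is
taken pre-log-transform, the literal reading of the filter; the boundary is
inclusive), computes pairwise Pearson correlation on log1p(TPM), clusters
on distance 1 − r with average linkage (the paper states no linkage; average
is the common choice for correlation heatmaps, and it is configurable), and
cuts at two groups.

## Differential expression model

The DE machinery is written from scratch rather than delegated, because the
quantities downstream (fold-change thresholds, baseMean, Holm adjustment)
are the analysis's substance:

* **Size factors**: median-of-ratios over genes observed in every sample.
* **Dispersion**: method-of-moments on normalized counts,
  α = max(0, (s² − μ)/μ²), optionally (and by default in `nb_de`) shrunk
  halfway toward a fitted a₀ + a₁/μ mean–dispersion trend. This is a
  lightweight stand-in for full empirical-Bayes shrinkage; acceptance is by
  simulation calibration (type-I error 0.05 ± 0.02 at n = 50) and recovery,
  not bit-equivalence with any external tool.
* **Wald test**: per-gene NB GLM, log link, design = intercept +
  double-mutant indicator, offset log(size factor), dispersion treated as
  known; fitted by IRLS with the linear predictor clamped to ±30 log units
  (so all-zero groups yield a bounded, flagged estimate rather than a
  divergence). p = two-sided normal tail of coef/SE.
* **Holm step-down** correction, implemented directly and tested against an
  independent oracle.
* **Classification**: strong DEG iff adjusted p ≤ 0.05, |log2FC| ≥ 3 and
  baseMean ≥ 10; weak DEG iff adjusted p ≤ 0.05 and |log2FC| ≥ 1.

`summarize_target_set` reports the target set's share of each sample's
transcripts and the median per-gene fold decrease, computed as mean
normalized counts in non-double grains over (double-mutant mean + ε) with
ε = 0.5 normalized counts: the double-mutant counts approach zero, and the
pseudocount keeps the ratio defined at the cost of a small downward bias
(visible in the synthetic runs, ~110 recovered vs 124 generated — within
the stochastic tolerance).

## Methylome classification and MPG selection

Only CG and CHG calls within annotated CDS are used (introns and UTRs are
unreliable for this purpose); CHH is ignored. A site is *informative* if at
least one read covers it. Per-gene levels are read-weighted means
(Σ methylated / Σ total over informative sites) by default — robust to
uneven coverage — with an unweighted per-site mean available since
"average methylation" does not specify weighting.

Classes (mutually exclusive, in order of precedence): `insufficient` if
either context has < 30 informative sites; `teM` if CG ≥ 0.40 and
CHG ≥ 0.40 (inclusive, per "at least 40%"); `gbM` if CG ≥ 0.40 and
CHG ≤ 0.05; `UM` if both ≤ 0.05; else `ambiguous`. Only the teM rule and
the 30-site rule are fixed by the study design; the gbM/UM bounds are
conventions carried from prior methylome work and are configurable.

Genes whose CDS overlaps a TE annotation by even a single base are flagged
and excluded from the core set (coordinates are BED 0-based half-open on
disk; adjacency is not overlap). MPG selection then requires teM class and
anther TPM ≥ 10 × (TPM + ε) in **each** of the eight vegetative tissues,
with ε = 0.01 TPM so that zero-expression tissues do not produce undefined
ratios; the tassel, which contains anthers, is excluded from the comparison
set.

## Timecourse normalization and smoothing

TPM assumes equal transcriptome sizes, which is wrong across pollen
development (a near-quiescent precursor and a mature grain differ ~3-fold
in total transcripts). `stage_scale_factors` multiplies each stage's TPM by
(mean total UMIs at that stage) / (mean at the mature-pollen reference) —
e.g. 133,905 / 377,873 = 0.354 for the bicellular-microspore stage —
preserving relative absolute abundance. Stage means are arithmetic means of
per-sample totals.

Trajectories are smoothed with a Gaussian kernel over per-sample pseudotime
(weights exp(−(t − ptᵢ)²/2h²), normalized). The bandwidth default is a
Silverman-style rule on the pseudotime spread (no bandwidth is stated in
the source analysis); the query grid defaults to 200 evenly spaced points,
or the sample pseudotimes themselves. Genes below 10 TPM in mature pollen
are excluded (strict <; exactly 10 is kept) as likely mapping artifacts.

## Morphometry

Particles are filtered to area 2000–14000 µm² and circularity 0.75–1.00
(inclusive windows, matching the image-analysis export). Areas are fitted
with a two-component Gaussian mixture by EM on the raw area scale (reported
summaries are in µm²; a log-scale fit is available by flag). Components are
labeled small-mean-first, making the fit invariant to initialization; the
verdict is "unimodal" when BIC favors one component or either weight falls
below 0.05. Volume inference assumes spherical grains, volume ∝ area^{3/2},
so an area ratio of 0.65 implies a 1 − 0.65^{1.5} ≈ 47.6% volume reduction.
How the original study quantified its secondary peak is not stated; the
mixture model is this package's formalization.

## The synthetic world

The generator's defaults *are* the stated experimental conditions: 26
analyzed grains plus 21 low-complexity grains; equal genotype probabilities;
58 target genes (half in 6 genomic clusters, as metadata) summing to 11.1%
of non-double transcripts and silenced 124.1-fold in double mutants (with
compositional renormalization, as real TPM data would show); depth means
549,559 and 5,444 UMIs; per-locus recombination probability 0.06
(≈ 3 ambiguous grains of 26 over two loci); BM/pollen stage means 133,905
and 377,873; a ¼ small-pollen component with 35% area reduction.

Where no value is stated, one realistic choice was made and frozen:
log-normal depth (sdlog 0.3, consistent with the reported 1.9e5–8.7e5
range), log-normal gene-abundance profiles, NB dispersion 0.1 (modest
biological variation among sibling grains), Poisson sentinel coverage
(mean 8) with 10% dropout, meiocyte/UM stage means of 60,000/90,000
(synthetic; only BM and pollen are reported), teM/gbM/UM site-level class
means drawn with clean margins around the 0.40/0.05 bounds, and normal area
components (7000 ± 600 and 4550 ± 450 µm²) with ~5% out-of-window debris.

What the generator does **not** emulate — and hence what a green recovery
test does not establish: mapping and barcode sequencing errors, UMI
collisions and PCR bias, batch effects, genuine biological covariation
among target genes beyond shared silencing, partial methylation boundaries
inside a CDS, and any genotype–morphology linkage at the single-grain level
(areas are generated marginally). Recovery tests demonstrate that the
algorithms invert the stated generative structure, not that they are robust
to artifacts absent from it.

## Numerical choices

* EM (complexity split, area mixture): deterministic initialization at the
  median split; relative log-likelihood tolerance 1e-8; SD floored at 1e-3
  of the data SD; component labels sorted by mean.
* NB IRLS: linear predictor clamped to ±30; convergence on max coefficient
  change < 1e-10; non-converged genes get NA p-values and are excluded from
  the Holm family (flagged).
* Boundaries are inclusive where the source wording says "at least"
  (teM 0.40, TPM sweeps, DEG thresholds, particle windows, the 500-TPM
  cluster filter) and strict where it says "under"/"<" (the 10-TPM pollen
  filter excludes below 10).
* All randomness flows through explicit integer seeds; the pipeline derives
  stage seeds as fixed offsets of the master seed, and identical
  configurations produce byte-identical JSON reports.

## Known limitations

* The DE dispersion estimator is deliberately simpler than full
  empirical-Bayes shrinkage; at very small sample sizes its Wald test can
  be mildly anticonservative. The null-calibration test pins type-I error
  at the scale it is used.
* Genotyping assumes the support table is already oriented
  (mutant-linked vs wild-type-linked read counts); phasing from raw parental
  alleles is out of scope.
* The fold-change summary's ε = 0.5 pseudocount biases very large folds
  downward by design; report it alongside the per-gene distribution.
* Two loci only; the sentinel framework does not generalize to arbitrary
  numbers of loci without extending the configuration type.
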