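---
title: "Methods: simulated RRBS and differential methylation calling with rrbspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated RRBS and differential methylation calling with rrbspipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbspipe)
library(data.table)
```

## What the package computes

`rrbspipe` implements a reduced representation bisulfite sequencing (RRBS)
analysis chain for comparing the DNA methylomes of pluripotent cell types:
per-CpG methylation quantification from methylated/total read counts,
differential methylation calling by Fisher's exact test with a
strong-effect threshold, aggregation of differential CpGs (DMCs) into
regions (DMRs), promoter CpG-density classification, overlap annotation
against repeats, imprinted clusters and germline DMRs (gDMRs), and
clustering with expression Z-score integration. A seeded synthetic RRBS
generator provides the input data, so every stage of the analysis can be
exercised end to end, with known ground truth, on any machine.

Throughout the package a CpG site is the 0-based position of the C of a
CpG dinucleotide on the forward strand; reads from the symmetric
reverse-strand G are pooled into the same site. All intervals are 0-based,
half-open.

## The statistical model

### Methylation levels and the coverage gate

For each CpG and sample the data are a pair (meth, total) of read counts.
Replicates are pooled by summing counts, so the merged level
`meth/total` is the coverage-weighted mean of the replicate levels. After
merging, only CpGs with total coverage at least 10 in *every* sample are
retained (inclusive bound); the gate guarantees every downstream level is
defined and keeps the Fisher test reasonably powered. Levels are exact
count ratios; no smoothing or imputation is applied.

Level categories use the fixed boundaries high >= 0.8,
0.3 <= intermediate < 0.8, low < 0.3. For the count denominators that
occur in practice (<= 10^6), a true ratio cannot fall within one
floating-point ulp of 3/10 or 4/5 without being equal to it, so plain
double comparison classifies the boundaries exactly.

### Strong DMCs

For two samples A and B at one CpG, the 2x2 table
(meth_A, unmeth_A | meth_B, unmeth_B) is tested with the two-sided
Fisher's exact test: conditional on the margins, the count meth_A is
hypergeometric, and the p-value sums the probabilities of all tables
whose point probability does not exceed that of the observed table (with
a 1e-7 relative tolerance for floating ties, the convention of standard
implementations). The test is computed by an in-package vectorised
enumeration that groups sites sharing margins, making genome-wide calls
cheap; it is cross-checked in the test suite against both an independent
binomial-coefficient enumeration and `stats::fisher.test`.

A site is a **strong** DMC when |level_A − level_B| strictly exceeds one
third *and* p < 0.05 (both strict). The effect-size comparison is done by
cross-multiplication against the rationalised threshold
(|meth_A·total_B − meth_B·total_A|·den > num·total_A·total_B), because the
float subtraction `25/30 - 15/30` lands one ulp *above* `1/3` and a naive
strict `>` would misclassify the exact boundary. Benjamini–Hochberg
q-values are reported alongside for transparency but do not gate the
call, which follows the raw-p protocol. Direction is the sign of
A − B ("hyper" means A above B, with the first-named sample as A).

### DMRs, merging, and region levels

Strong DMCs of one direction on one chromosome are chained whenever
consecutive positions are at most `max_gap = 300` bp apart; chains with
at least `min_cpgs = 3` CpGs become DMRs spanning the first to last CpG
(end = last position + 1). These two chaining parameters are pipeline
defaults in common RRBS practice, exposed in the configuration — the
upstream protocol delegates them to its caller's defaults without
printing values. A DMR's level per sample is the *unweighted mean* of its
constituent CpG levels.

When DMR sets from two comparisons are combined, intervals overlapping by
at least 1 bp are unioned transitively and the merged region's level is
re-computed per sample as the unweighted mean over *all* gated CpGs inside
the merged interval; DMRs that overlap nothing pass through unchanged.

### Promoters and CpG-density classes

Promoters are TSS ± 1 kb (symmetric, strand recorded but not used for the
interval; clipped at contig ends). CpG density classes slide 500-bp
windows at 5-bp steps: a promoter is HCP if some window has CpG
observed/expected >= 0.75 and GC >= 0.55, LCP if no window reaches
O/E >= 0.48, ICP otherwise, with
O/E = (N_CpG · L)/(N_C · N_G) and O/E defined as 0 when the window lacks
C or G. Dinucleotides are counted only when fully inside the window. At
step 1 the scan is exhaustive and equals a brute-force oracle by
construction; step 5 is the speed/accuracy default.

### Annotation

Each site receives exactly one exclusive location label by the precedence
promoter > exon > intron > intergenic (the protocol does not state a
tie rule; most-regulatory-first is the standard choice and is applied
uniformly). Overlaps with repeats, imprinted clusters and gDMRs are
non-exclusive flags. A DMR is labelled promoter-DMR (or imprinted,
gDMR- or repeat-overlapping) when it overlaps the feature by >= 1 bp;
intervals are half-open and overlap is strand-blind, consistent with
strand-pooled methylation.

### Clustering and expression integration

Promoter-DMR level matrices are clustered with K-means (K = 3): k-means++
seeding, Lloyd iterations, squared-Euclidean distance, best of 10
restarts by total within-cluster sum of squares, empty-cluster runs
re-seeded; the seed and restart count make runs reproducible, and rows
within a cluster are ordered by identifier. K-means runs on the raw level
matrix (the heatmap it feeds displays methylation ratios), not on
row-scaled values. Hierarchical clustering uses average linkage on
Euclidean row distances — the linkage/distance pair is a package default,
exposed in the API, since the protocol does not state one — and asserts
the monotonicity of merge heights.

Expression tables (FPKM, genes × samples) are converted to per-gene
Z-scores with the sample (n − 1) standard deviation; with three cell
types the denominator choice is material, and n − 1 makes each surviving
row have s.d. exactly 1. Genes with zero FPKM in every sample are removed
before scaling ("no expression" is exact zero; no near-zero threshold is
applied); constant non-zero rows cannot be scaled and are removed with a
logged count.

## The synthetic data generator

The generator emulates the statistical structure the analysis assumes,
not real genome sequence:

* **Genome**: random contigs with base composition A/T-rich (GC ≈ 0.4)
  and 80% of background CpG dinucleotides removed, mimicking the
  genome-wide CpG depletion of mammalian DNA. MspI sites (CCGG) are
  planted at spacings uniform on 180–360 bp so that the in-silico digest
  yields fragments concentrated in the 170–370 bp size-selection window,
  as in an RRBS library.
* **Features**: promoters spanning exactly TSS ± 1 kb (a configurable
  fraction rewritten with a CpG-island-like core: dinucleotide sampling
  giving GC ≈ 0.65 and CpG O/E well above 1, so a 500-bp window passes
  the HCP rule), gene bodies with exons and introns, LINE/SINE/LTR
  repeats, and imprinted clusters each containing a gDMR sub-interval.
  Feature blocks are placed without overlap by rejection sampling; an
  impossible packing raises a sizing error.
* **Methylation states**: each cell type is a Beta-mixture profile per
  feature class — with probability `weight_high` the CpG's true level is
  drawn from Beta(18, 2) (mean 0.9), otherwise Beta(1.5, 15) (mean 0.09).
  The shipped profiles encode a hypermethylated, bimodal "4F-like" type
  (background weight 0.25; repeats/gDMRs 0.85–0.90), a hypomethylated
  "ESC-like" type (0.02; 0.05) and an intermediate "C-like" type (0.12;
  0.40). These weights are generator settings chosen once so that the
  genome-wide high-methylation (>= 0.8) fractions come out near
  25% / 12% / 2% and repeats/imprinted regions show the hyper–intermediate–
  hypo ordering the comparisons are designed to detect; they are not
  measurements of any real cell line. When features nest, the most
  specific class wins by the fixed precedence gDMR > imprinted_cluster >
  promoter > repeats > exon > intron > other.
* **Counts**: only CpGs inside size-selected fragments are covered. Per
  CpG and sample, total ~ Poisson(30) (optionally Gamma-overdispersed
  across replicates, dispersion 0.05 by default) and
  meth ~ Binomial(total, q) with
  q = m_true + (1 − m_true)(1 − conversion_efficiency): an unconverted
  unmethylated cytosine reads as methylated, so incomplete conversion
  (default efficiency 0.995) inflates apparent methylation slightly. No
  sequencing-error, PCR-duplicate or paired-end geometry model is
  included.

What passing tests on these data show — and do not show. The generator
reproduces coverage structure, replicate noise, bimodal cell-type
contrasts and feature nesting, so it validates the *logic* of gating,
testing, chaining, merging, classing and clustering. It does not
reproduce real sequence composition, SNPs, non-CpG methylation,
strand-specific artefacts or alignment error, so test results say nothing
about upstream read processing, and absolute counts of DMCs/DMRs on real
libraries will differ from the synthetic ones.

## Numerical and design choices

* Fisher p-values are exact hypergeometric sums; ties use the 1e-7
  relative tolerance; p is clipped into (0, 1].
* The strong-effect threshold is stored as a rational (continued-fraction
  approximation of the configured value) and compared by
  cross-multiplication, avoiding boundary misclassification from float
  round-off; the exact value "one third" is therefore never strong.
* Size-selection bounds (170 and 370 bp) are inclusive on both ends.
* Spearman correlation is Pearson on mid-ranks (average ranks for ties),
  computed per pair over sites defined in both samples — after the
  coverage gate that is the full retained set, which is the only universe
  on which all samples are defined. Fewer than 3 common sites is an
  explicit error.
* Histograms use equal-width bins on [0, 1] with a right-closed last bin
  so that level 1 is counted.
* Degenerate inputs fail loudly: empty Fisher margins, levels at
  total = 0, TSS outside contigs, unknown replicate ids, profiles missing
  a feature class, and configurations missing any threshold are all
  rejected before computation.

## Problem sizes and reproducibility

The default study design (`default_config()`) simulates two 500-kb
contigs, three cell archetypes with two replicates each at 30x coverage —
about 12,000 gated CpGs — which keeps a full pipeline run in the
single-digit seconds while leaving every stage non-trivially populated.
The test suite and the acceptance script scale the same machinery up or
down per property (e.g. a 2-Mb genome with 50 planted DMRs of true effect
0.5 for recovery, 12,000-site null panels for type-I error, ~1.2x10^5
enumerated tables for the Fisher oracle). Every random draw flows through
a user-supplied seed; re-running any stage, or the whole pipeline, with
the same configuration and seed is byte-identical on the tabular outputs.

## Known limitations

* The Fisher-based caller models sampling noise only; there is no
  beta-binomial layer for biological variance between replicates beyond
  count pooling, and no smoothing-based DMR detection.
* DMC-to-DMR chaining parameters are heuristics; regions separated by
  coverage gaps larger than `max_gap` are reported as separate DMRs.
* The imprinted/gDMR annotation uses the synthetic catalogue's
  coordinates; no external atlas is downloaded or bundled.
* GO or pathway enrichment of DMR-associated genes is out of scope.

## A minimal run

```{r, eval = FALSE}
cfg <- default_config(seed = 1)
res <- run_pipeline(cfg, "rrbspipe_demo")
res$manifest$stages$quantify
res$quant$cats
```
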