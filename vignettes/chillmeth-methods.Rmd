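---
title: "Methods: windowed DMR calling and methylome-transcriptome integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed DMR calling and methylome-transcriptome integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific setting

Perennial fruit trees arrest growth in winter buds and release dormancy only
after accumulating enough cold, conventionally measured as chilling hours
(CH): hours strictly below 7.2 °C. Genotypes differ widely in their chilling
requirement (CR), the CH accumulation at which at least half of the buds
resume growth under forcing conditions. `chillmeth` implements the analysis
path used to ask how the bud methylome and transcriptome change along a
chilling time course in two genotypes with contrasting CR: whole-genome
bisulfite calls are quantified in fixed windows and screened for
differentially methylated regions (DMRs), count matrices are screened for
differentially expressed genes (DEGs), and the two are joined through gene
proximity, cross-genotype conservation and methylation–expression
correlation.

# Windowed DMR calling

## The window statistic

Chromosomes are tiled from position 1 in non-overlapping 100-bp windows by
default (`tile_windows()`; a sliding step `1 <= step <= width` is exposed,
but overlapping windows would make neighbouring tests strongly dependent and
strain the FDR correction, so disjoint tiles are the default). Per sample,
the methylation state of a window is a **log2 enrichment**:

$$E = \log_2 \frac{(m_w + c)/L_w}{(M + c)/L},$$

with \(m_w\) the methylated-call count inside the window, \(L_w\) the window
width, \(M\) the sample's genome-wide methylated-call count, \(L\) the
genome length, and \(c = 0.5\) a pseudocount that keeps empty windows
finite. "Density" here is methylated **calls** per bp: the ratio of an
observed window density to an overall sample density only makes sense when
both count the same objects, and the overall per-sample quantity is a call
density. The alternative (methylated positions per covered position) is
deliberately not used. Both strands are pooled.

Only cytosines covered by at least five reads enter quantification; the
filter lives in the reader (`read_cytosine_report(min_coverage = 5)`) so
that every downstream stage sees the same filtered universe, and the
genome-wide totals \(M\) are computed over the same filtered calls. Windows
with fewer than 20 methylated cytosines are discarded
(`filter_windows()`); a methylated cytosine is a distinct position/strand
with at least one methylated call, pooled over the union of the experiment's
samples. The union is used because a condition that gains methylation should
not be silenced by a baseline condition that lacks it; a stricter per-sample
mode is exposed for users who want symmetric evidence.

## Testing

Replicate-level \(E\) values are compared across chilling conditions with a
classical one-way fixed-effects ANOVA (`stats::oneway.test`, equal
variances), three replicates per condition in the emulated design. Two
degenerate conventions: all-equal values give \(p = 1\), and perfect
separation (zero within-group variance) reports the smallest positive
representable p-value rather than 0. P-values are adjusted by
Benjamini–Hochberg step-up (`stats::p.adjust`) over exactly the filtered
window set. A window is a DMR when \(q < 0.01\) **and** the largest
difference in condition-mean enrichment between any two conditions exceeds
3 log2 units (both exposed; strict inequalities). Direction is reported per
condition-vs-baseline contrast — hypermethylated if the contrast's mean
difference is positive — for windows whose contrast difference also clears
the fold-change gate, which reproduces per-contrast hyper/hypo tallies.

Context-specific calling (`call_dmrs_by_context()`) repeats the entire
procedure with calls and totals restricted to CpG, CHG or CHH, so a window
may be a DMR in several contexts. On data whose calls are all one context
the per-context and all-context calls coincide exactly (a property test).

## Profile utilities

DMR condition profiles can be ranked by variance (`top_variance()`, ties
broken lexicographically by id for determinism) and grouped into
subclusters by k-means on per-item z-scored profiles
(`cluster_profiles()`), with the workflow defaults of 16 DMR subclusters
and 10 co-expression subclusters. K-means runs under a fixed seed and fixed
restarts; the same seed gives identical partitions. When `k` equals the
item count the degenerate all-singletons partition is returned directly.

# Differential expression

Between-sample scaling uses TMM (trimmed mean of M-values), implemented
in-package following the published procedure: reference sample by
75th-percentile count fraction closest to the mean; gene-wise log-ratios
and abundances over genes non-zero in both samples; double trimming (30% on
M, 5% on A); precision-weighted mean with inverse delta-method binomial
variances; factors rescaled to geometric mean 1. The test suite checks it
against both a loop-coded oracle of the formula and an independent
implementation (edgeR's) on random matrices — they agree to machine
precision.

The DEG engine is a documented stand-in for the NB machinery the field's
packages provide: per gene, a negative-binomial likelihood-ratio test of
the two-group effect with `log(effective library size)` offsets
(`stats::glm.fit` with `MASS::negative.binomial`). The dispersion is common
across genes, pooled by method of moments: per-gene moment estimates
\((s^2 - \bar z)/\bar z^2\) on normalised counts, clamped to a wide band so
no single gene dominates, averaged over genes with mean at least 5. This
pooling is stable from a few dozen genes up (the naive ratio-of-sums
variant is dominated by the most-expressed genes and badly overestimates on
small panels). A conservative `tagwise-moments` mode takes, per gene, the
larger of the common and the gene's own estimate. The contract of this
engine is calibration — near-uniform null p-values, controlled empirical
FDR, high recovery of planted effects — not numerical identity with any
named package.

Calls follow the usual thresholds: `up` if \(q < 0.01\) and
\(\log_2 FC \ge 1\) (two-fold), `down` mirrored, else `ns`; BH is applied
within each contrast separately because the workflow reports per-contrast
DEG counts. The log2 fold-change is computed from group means of normalised
counts with a 0.5 pseudocount, before any shrinkage, so the two-fold gate
acts on raw normalised means. FPKM (`fpkm()`), sample-level PCA on
`log2(x+1)` with per-gene centring (`pca_summary()`), ΔCt relative
expression, chilling hours (strictly below 7.2 °C) and the 50% bud-break CR
rule round out the layer.

# Integration

DMRs are linked to genes whose span, extended by 2,000 bp on both sides,
they intersect (`link_dmrs_to_genes()`, GenomicRanges overlap); relative
position (upstream/gene-body/downstream) is strand-aware with a signed
distance. Quadrant tables (`quadrant_overlap()`) cross DMR direction with
DEG call per contrast; genes linked only to direction-less DMRs are not
counted, genes missing from the DEG table go to an explicit `no_test`
tally, and genes linked to DMRs of conflicting direction are counted once
per direction and flagged. Conservation across genotypes
(`conserved_patterns()`) requires the same class (by default
hyper∩down or hypo∩up) in at least one contrast of **each** genotype — the
contrast index may differ, because chilling temporality is
genotype-specific.

The correlation screen computes Pearson r between a DMR's per-condition
mean enrichment and the linked gene's per-condition mean expression,
over the conditions shared by the two assays (the methylome and RNA designs
need not have the same condition count; at least 3 shared points are
required), retaining links with \(r \le -0.5\). Correlation is computed on
condition means, not replicate pairs: the two assays share conditions, not
samples. A gene with several linked DMRs yields one record per DMR;
`closest_only` restricts to the nearest DMR (ties by id). Zero-variance
profiles have no defined r and are excluded with a warning rather than
silently scored. Term enrichment is a generic hypergeometric upper-tail
test over a user-supplied gene-to-term map with BH adjustment — no ontology
download or graph propagation.

# The synthetic-data generator

`simulation_design()` fixes the emulated study: two genotypes — a low-chill
one sampled at 0/173/348/516 CH (RNA at 0/348/516) and a high-chill one at
0/443/1,295/1,637 CH for both assays — three replicates per condition, one
200-kb chromosome (2,000 windows), 500 genes, context baselines CpG 0.60 /
CHG 0.35 / CHH 0.10 (typical plant methylome rates; the relative shares of
methylated sites among contexts reported for bud tissue are shares, not
per-context rates, so they are not used as baselines), negative-binomial
coverage (mean 20, size 5), 40 planted DMRs (CHH-dominant, proportion shift
0.4 switching on at the second condition — methylation changes appear
between the first two chilling points in this system — 70% hyper), 50
planted DEGs (four-fold, onset at the second condition), and 10 planted
anti-correlated pairs (methylation ramping up monotonically while the
gene's expression ramps down by 2 log2 units). Proportions are clipped to
[0.01, 0.99] to avoid degenerate binomials. All randomness flows from one
master seed through fixed per-stage offsets, so each stage is independently
reproducible and the whole experiment is a deterministic function of
`(seed, design)`.

Two planting constraints avoid degenerate truth: planted windows must carry
at least 20 cytosines of the planted context (otherwise the
methylated-cytosine window filter makes the planting undetectable **by
construction**, which would measure the sequence composition of a random
window rather than the caller), and pair genes must have a baseline mean of
at least 20 expected counts (the planted monotone profile is meaningful
only when replicate shot noise on the log scale stays moderate, about 0.2
at these settings).

What the generator does **not** emulate: read-level data (no FASTQ, no
alignment or bisulfite-conversion error), mappability and GC bias,
spatially correlated methylation beyond the planted windows, isoform
structure, batch effects, and biological replicate heterogeneity beyond the
NB dispersion. Passing recovery tests therefore demonstrates the
correctness and calibration of the procedure under its own assumptions, not
performance on real libraries.

## Detection thresholds on synthetic data

With a CHH baseline of 0.10 and the planted shift of 0.4, the largest
enrichment difference a planted CHH window can reach in CHH-restricted
quantification is \(\log_2(0.5/0.1) \approx 2.32\) log2 units. The
package-default fold-change gate of 3 is calibrated to real methylomes,
where DMRs typically rise from near-zero background; on the synthetic
conditions it is unattainable by design. The recovery analyses therefore
use `min_delta = 1.5`, chosen a priori midway between the null
fluctuation of condition-mean enrichment (~0.4 at 3 replicates and these
coverages) and the planted shift. Null calibration is unaffected: under a
no-effect simulation the fraction of windows at \(q < 0.01\) stays at the
permilles regardless of the gate.

# Numerical choices and conventions

* Coordinates are 1-based inclusive everywhere; BED input is converted at
  the boundary, and the BED-like DMR output converts back.
* Context token `CG` is normalised to `CpG` on input.
* Targeted region summaries are read-weighted
  (\(100 \sum m / \sum (m+u)\)), not cytosine-averaged: amplicon assays
  report call-level percentages, and read-weighting keeps the partition
  additivity property (whole = sum of parts).
* Zero-variance ANOVA windows give \(p = 1\); perfect separation gives the
  smallest positive double; p-values never print as exactly 0.
* Windows without qualifying calls in a sample get their enrichment from
  the pseudocount rather than being dropped; dropping would make the tested
  window set sample-dependent.
* k-means and every simulation stage run under `with_seed()`, which
  restores the caller's RNG state.
* The pipeline writes a manifest of MD5 hashes of every output plus the
  full parameter echo; reruns with an identical configuration are
  byte-identical, and the thread setting does not affect any result.

# Problem sizes

The shipped analyses are sized for a desk machine: null calibration uses
one 500-kb chromosome (5,000 windows, 12 samples) and 2,000 null genes;
recovery uses the 200-kb desk-scale design above; the pipeline determinism
fixture uses a 60-kb chromosome. A full desk-scale simulate-to-integrate
run completes in about a minute; the whole test suite in a few minutes.

# Known limitations

* The common-dispersion NB test does not shrink per-gene dispersions;
  strongly heterogeneous real data would warrant the `tagwise-moments`
  mode or a dedicated DE package.
* ANOVA on log2 enrichment assumes approximate normality of replicate
  enrichment values; at very low coverage this is rough.
* The hypergeometric enrichment treats terms independently (no ontology
  structure).
* `conserved_patterns()` matches gene identifiers across genotypes and
  therefore requires a shared annotation.
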