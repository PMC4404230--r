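---
title: "Group-specific CNV discovery from extreme-phenotype cohorts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-specific CNV discovery from extreme-phenotype cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extremecnv)
```

## The design this package implements

Selective genotyping keeps mapping power at a fraction of the genotyping
cost: instead of assaying a whole population, only the extreme tails of a
quantitative phenotype are typed. `extremecnv` implements the copy-number
variant of that design. Two small groups — here, boars from the upper and
lower 10% of the direct-boar-effect (DBE) distribution, i.e. the number of
piglets per litter a boar adds relative to the population mean — are
genotyped on a SNP array, and their log R ratio (LRR) profiles are searched
for copy number variants (CNVs) carried by only one group. A merged,
group-labelled catalogue of CNV regions (CNVRs) is then annotated against
QTL, gene and miRNA tracks and validated in an independent cohort and by
qPCR arithmetic.

The LRR at a marker is `log2(R_observed / R_expected)`; under the additive
noise model used throughout, two copies give LRR ≈ 0, a one-copy deletion a
negative shift and a duplication a positive shift. All genomic coordinates
are 1-based inclusive internally; BED exports are 0-based half-open.

## The signal model and its assumptions

`simulate_cohort()` generates LRR as

```
LRR[s, m] = delta[s, m] + w_b * (gc_m - mean(gc)) + beta_b + N(0, sigma^2)
```

where `delta` is the copy-state shift inside an implanted CNV carried by
sample `s` (0 elsewhere), `w_b` a per-batch genomic-wave slope in centered
GC fraction, `beta_b` a per-batch additive intensity shift, and `sigma` the
marker-level noise SD. The same additive, locally-constant-mean,
independent-Gaussian-noise model underlies the segmentation: markers are
assumed exchangeable within a copy-number state, and noise is assumed
homoscedastic within a sample.

Generator defaults are the study conditions the package targets, chosen
once: 11 high / 10 low discovery samples and 8 / 9 validation samples; group
DBE means ± SD of 2.83 ± 0.61 and −2.72 ± 0.79 piglets (2.38 ± 0.36 and
−3.38 ± 0.97 for the validation groups); `noise_sd = 0.1` LRR units;
one-copy shifts of −0.45 (loss) and +0.30 (gain); two batches with an
additive shift of 0.05 and wave slopes of 0.02. The loss/gain shifts are
array conventions for one-copy changes — the calling thresholds below are
the quantities with empirical standing, per-copy LRR magnitudes are
platform-dependent. The wave slope is kept below the wave-flagging threshold
so a default cohort is wave-clean, while the batch shift is large enough for
PCA to separate the batches at realistic marker counts.

What the generator deliberately does **not** emulate: B-allele frequencies,
raw X/Y channel intensities, linkage disequilibrium between markers, breed
stratification, heteroscedastic or heavy-tailed noise, and real genome
coordinates. Consequences for interpretation: passing tests show the
pipeline recovers additive mean shifts under Gaussian noise with known
ground truth; they say nothing about BAF-informed callers' advantages,
wave-correction quality on real hybridization chemistry, or the behaviour of
the thresholds on other platforms.

## Segmentation: exact DP, BIC model selection, pairwise pruning

For one chromosome of one sample, `optimal_segment()` solves the
least-squares changepoint problem exactly: for each candidate number of
segments `k` up to `max_segments_per_chromosome`, dynamic programming over
prefix sums finds the cut-points minimizing the within-segment sum of
squared deviations, subject to `min_markers` per segment. The optimum is
exact, not heuristic — the test suite checks it against exhaustive
enumeration of all cut placements for n ≤ 20, k ≤ 4.

Two decisions here were genuinely open:

* **Choice of k.** Residual sums of squares decrease monotonically in k, so
  "best RSS" always selects the cap and maximizes overfitting; the
  subsequent significance test between adjacent segments is computed on the
  same data that placed the cuts, so overfitted cuts inflate the false-call
  rate substantially. We therefore select k by Gaussian BIC,
  `N log(RSS_k / N) + p k log N`, with `p = 2` parameters per extra segment
  (a mean and a boundary) in the univariate path and `p = ns + 1` in the
  joint path over `ns` samples. A zero-residual (noiseless) series takes
  the smallest k achieving it, so a constant series yields no cut-points
  and a clean step exactly one. The DP cap (default 20 segments per
  chromosome) remains as a cost bound and is exposed as a parameter.
* **The pairwise test.** Adjacent segments are compared by a
  pooled-variance two-sample t-test (segments share a noise model within a
  sample, so pooling is appropriate; Welch would only lose power at these
  segment sizes). `prune_cutpoints()` removes the cut with the largest
  p-value while that p exceeds `max_pairwise_p` (default 0.005),
  recomputing after each removal, so on exit every adjacent pair differs at
  p ≤ 0.005. Degenerate segments need a convention: when the pooled
  within-segment variance is zero the p-value is taken as 0 if the means
  differ and 1 if they are equal. This makes noiseless fixtures behave
  (equal flanks merge, true steps survive) but has a practical corollary:
  with `min_markers = 1`, single-marker segments always have zero variance,
  so an isolated extreme marker can never be pruned away. The pipeline
  default is therefore `min_markers = 3`; 1 remains available for users who
  want single-marker sensitivity and accept the false-call cost.

A caveat worth stating explicitly: the pruning p-value is a *per-pair*
level, not a family-wise one. With three arbitrary cut-points on pure
noise, "any cut survives" is the event that the minimum of three dependent
p-values falls below the threshold after backward elimination, which occurs
at roughly three times the per-pair level (~1.5% at 0.005), while a single
cut is retained at the nominal rate. The test suite pins both behaviours
against an independent re-implementation of the elimination loop.

Calling applies the segment-mean filters: mean < −0.15 is a loss,
mean > 0.1 a gain, with at least `min_markers` markers. These thresholds
are in LRR units and are the operational definition of "present"; they are
deliberately asymmetric (a one-copy loss moves LRR further than a one-copy
gain).

Because threshold calling is not shift-invariant, `run_discovery()` centers
each sample's LRR at its genome-wide median before segmentation (QC runs on
the raw signal). Without this, an additive batch offset eats into one
threshold: at +0.05 that is half the gain margin, and long, slightly
positive chromosome-leading segments in shifted samples get called. The
median is robust as long as well under half the genome is copy-altered,
which holds by orders of magnitude in this design.

## The multivariate path and group specificity

`multivariate_segment()` segments a whole group with common cut-points by
summing the DP cost over samples, prunes on the cross-sample mean profile,
and accepts a segment as a group call only when *every* sample's segment
mean is beyond the same threshold — the operationalization of "present in
all samples" (the quantity is never defined more finely by the design this
mirrors). A single-sample group reduces exactly to the univariate path.

`group_specific_multivariate()` runs the high group, the low group and the
pooled set, then accepts a group call only if it overlaps no same-status
call from the other group's run and no call at all from the pooled run.
The same-status qualification matters: an event present in both groups
with *opposite* status (gain in one, deletion in the other) is a legitimate
finding — there is no threshold-consistent pooled call for it — and both
calls are retained and later labelled as an opposite-status (`HL`) region.
The pipeline splits the cohort by batch cluster before the multivariate
runs, so batch offsets cannot masquerade as common segments.

## CNVR merging, labels, naming

`merge_calls()` merges calls on the same chromosome that overlap by at
least 1 bp, transitively; abutting intervals (end + 1 = start) are *not*
merged. Merging is order-invariant and idempotent. A region's label is `H`
if every member call comes from high-group carriers, `L` if all low, `HL`
when both groups are present with strictly opposite statuses, and
non-specific otherwise (present in both groups with the same or mixed
status; such regions stay in the catalogue but are excluded from the
group-marker lists). Names are `CNVR<number><suffix>` in ascending
(chromosome, start) order — deterministic for a given catalogue, but not
comparable across catalogues. The minimum carrier count for a
group-specific region is 1: in an 11-versus-10 design a single-animal
univariate call is already the finest evidence unit available, and stricter
filters are a one-line post-hoc subset of the catalogue.

## Annotation statistics

Reproduction-QTL enrichment uses a 2×2 table of QTL *records* (not traits,
not covered bp) — class (reproduction vs other) by overlap with any CNVR —
tested with the Yates-corrected chi-square on 1 df (the correction clamps
to zero when |ad − bc| ≤ N/2; any zero margin returns a not-testable
verdict). Record-level counting follows how QTL databases enumerate
entries; per-trait counting is a reasonable sensitivity analysis the user
can run by collapsing the track first.

Gene-set enrichment is the upper-tail hypergeometric test on user-supplied
category tables (GMT-like), with C = category size in the reference,
O = observed overlap, E = C·n/N, R = O/E and Benjamini–Hochberg adjustment
across tested categories. The reference gene universe (or just its size N)
is user-supplied: enrichment against a web service's hidden reference is
not reproducible, so the package refuses to guess one.

## Validation arithmetic

`validate_cohort()` computes, per CNVR, each validation sample's mean LRR
over the region's markers and a two-sided Mann–Whitney U test between the
validation groups; "replicated" means p < 0.05, "present" means at least
one validation sample re-calls a non-neutral status by the mean thresholds.
At 9-versus-8 the exact test's floor under complete separation is
2/C(17,8) ≈ 8.2e-5, and its attainable null rejection rate at 0.05 is
0.0464 — both pinned in the tests. Regions covering no validation marker
are reported not-testable rather than silently dropped.

qPCR efficiency is estimated LinRegPCR-style: subtract a baseline (mean of
the first 3 cycles), fit log10 fluorescence on cycle over every sliding
window of 4–6 cycles with positive signal, keep the window with the best
R², require R² ≥ 0.99, and report 10^slope as the per-cycle fold change.
Efficiencies are averaged per locus (per-locus means match how replicate
wells are summarized in practice); triplicate Ct values are aggregated by
mean with an SD > 0.5 cycle flag. The Pfaffl ratio
`E_t^dCt_t / E_ref^dCt_ref` classifies as loss below 0.75 and gain above
1.25 — midpoints between the expected 1-, 2- and 3-copy ratios (0.5, 1.0,
1.5); the bounds are configurable since real assays calibrate them.

## Numerical conventions

* Zero-variance / zero-residual comparisons use a relative tolerance of
  1e-10 on the data scale.
* Ties in backward elimination (equal p-values) remove the left-most cut
  first; `which.max` makes this deterministic.
* `select_extremes()` breaks phenotype ties by original index order
  (stable sort), so tail membership is reproducible.
* All randomness flows from explicit integer seeds; identical seeds give
  bitwise-identical cohorts, catalogues and output files.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen to keep
a full run in tens of seconds while leaving all operating characteristics
measurable: cohorts of 17 autosomes × 150 markers (2,550 markers at 50 kb
spacing, about 1/20 of a 60k chip) with the full 33-region implant design,
plus smaller fixtures (5 × 80–120 markers) for plumbing tests; simulation
suites use 100–1,000 seeded replicates depending on the property. The
segmentation oracle comparisons stay at n ≤ 20 where exhaustive enumeration
is exact.

## Known limitations

* Calling is mean-threshold-based on LRR only; no BAF, no integer copy
  number, no HMM smoothing. Mosaic or small-effect events below the
  thresholds are invisible by construction.
* The pairwise-p pruning controls a per-pair, not family-wise, error rate
  (see above); the BIC selection in front of it is what keeps the
  genome-wide false-call rate low (~0.02 per sample-chromosome at the
  default noise level, as measured by the test suite).
* "Present in all samples" in the joint path is strict: one group member
  whose segment mean lands inside the neutral band vetoes the group call.
  That is the intended behaviour of the design being mirrored, but it makes
  joint calls conservative when group membership is noisy.
* The synthetic cohort's independence assumptions (no LD, no breed
  structure) mean recovery rates measured here are upper bounds for real
  arrays.
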