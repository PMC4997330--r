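---
title: "DHS position inside bidirectional promoters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DHS position inside bidirectional promoters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdpc)
```

## The question the pipeline answers

A bidirectional promoter (BDP) is the intergenic interval between the
transcription start sites (TSSs) of two adjacent, divergently oriented
(head-to-head) genes, here restricted to at most 1 kb. In rice and other
plants many such pairs are coexpressed, and open-chromatin regions —
DNase I hypersensitive sites (DHSs) — inside the BDP are candidate shared
regulatory elements. This package implements the positional analysis of
DHSs within BDPs: where a DHS sits relative to the two TSSs, and how that
position relates to (i) expression level of the flanking genes, (ii)
coexpression of the pair, and (iii) nucleosome and histone-mark occupancy
around the promoter.

The pipeline consumes standard files — GFF3 gene models, BED peak calls,
a gene-by-library FPKM table, and a fragment BED for occupancy — and never
re-implements the upstream steps (peak calling, read alignment, FPKM
estimation) that produce them.

## Pair identification

Internally all coordinates are 0-based half-open; GFF3 input is converted
on read and the published pairs table is written back 1-based inclusive.
The TSS is the first transcribed base of the gene model: `start` on the
plus strand, `end - 1` on the minus strand (one TSS per gene;
isoform-resolved TSSs are out of scope).

Two genes form a pair when they are adjacent in `(chrom, start)` order,
the left gene is on the minus strand and the right gene on the plus
strand, the TSS-to-TSS distance lies in (0, 1000] bp, the bodies do not
overlap, and no third gene body intrudes into the intergenic interval.
Two of these conditions are our own resolutions of genuinely open
questions:

* **Overlapping divergent genes** (negative TSS distance) are excluded:
  the analysis concerns positive intergenic promoter intervals only.
* **Intruding third genes** disqualify a pair, because the interval
  between the TSSs is then not a promoter-only region. Annotation sets
  with nested gene models would otherwise produce intervals crossing a
  gene body.

BDPs are classed by length into I (0, 250], II (250, 500] and
III (500, 1000] bp. The boundaries are upper-inclusive so 250 and 500 fall
in exactly one class; the source convention ("0–250", "250–500",
"500–1000") does not state boundary membership, and any consistent choice
changes at most a handful of pairs.

## DHS classification

A peak belongs to a BDP when its *midpoint* lies inside the interval
(half-open; straddling peaks are not clipped). Each BDP then falls into
one of four categories: `one_mid` (a single, centred peak), `one_amesial`
(a single off-centre peak), `bi` (two or more peaks), `none`.

The centred/off-centre boundary is the one genuinely undefined quantity in
this analysis: "near the middle" has no published threshold, and the
original contingency table cannot be regenerated exactly without it. We
therefore expose it as `mid_fraction` in `classifier_config()`: a single
peak is `one_mid` when its midpoint is within `mid_fraction * bdp_length`
of the BDP centre. The default 0.25 (the central half of the BDP) is a
reporting choice, not an estimate of the original threshold; the
classifier is monotone in it (shrinking `mid_fraction` can only convert
`one_mid` calls to `one_amesial`, never the reverse), and the synthetic
round-trip tests pass for any value in (0.1, 0.4).

Whether partially overlapping peaks were merged before counting is equally
unstated; the default is no merging (`merge_gap = 0`), with an optional
gap-based union for peak callers that fragment a single open region.

For single-peak BDPs the gene with the smaller midpoint-to-TSS distance is
labelled *proximal*; an exact tie goes to the left gene, a deterministic
rule that only matters on measure-zero synthetic cases.

## Expression statistics

Group comparisons use two-sided two-sample Kolmogorov–Smirnov tests at
`alpha = 0.05` on per-gene summaries. Each gene is summarised by its mean
FPKM across libraries, transformed as `log(FPKM + 1)`; whether the
original figures used the across-library mean or a single seedling
library is not stated, so a single named library is supported as an
alternative. The K-S statistic is the ECDF sup-distance evaluated at all
pooled sample points (`stats::ks.test`), with asymptotic p-values: at the
group sizes involved (hundreds of genes) the exact-vs-asymptotic
difference is negligible, and the asymptotic test's type-I error is
checked by simulation in the test suite (≈0.043 at n = 200 per group).

Pair coexpression is the Pearson correlation of the two genes' FPKM
vectors across libraries (11 in the emulated design). Three filters
apply, in order: genes absent from the matrix (pair skipped with a
warning), genes with FPKM = 0 in every library (pair excluded and
counted), and zero-variance genes (correlation undefined, excluded).
Presence/absence (digital gene expression) libraries — columns whose
values are all 0/1 — are dropped from the correlation by default, because
mixing binary and continuous scales distorts the product-moment
statistic; they can be kept with `exclude_binary = FALSE`.

The random control is 1000 non-adjacent gene duos drawn (seeded, without
replacement of duos) from genes outside every BDP pair. "Coexpressed" has
no published cutoff; `pcc_threshold = 0.5` is the exposed default and is
written into every output that uses it.

The expression-matched unidirectional control matches each BDP gene to an
unused pool gene from the same decile of mean `log(FPKM + 1)`, falling
back to the nearest non-empty decile when one empties (counted and
reported).

## Metagene occupancy profiles

Occupancy is computed from fragment midpoints (the midpoint of each
mapped read/fragment defines its position; single-end data must be
midpoint-shifted before loading). A region is tiled left-to-right in
half-open 50-bp windows and each window's value is

    count / (width_bp * total_mapped / 1e6)

i.e. reads per bp per million mapped reads. Summing `value * width`
over windows and multiplying by `total_mapped / 1e6` reconstructs the raw
in-region count exactly — a conservation identity the tests assert.

Per pair, the profiled region is 1 kb downstream of the left TSS, the BDP
interval, and 1 kb downstream of the right TSS. The member of the pair
with the higher mean FPKM is aligned to the right: the vector is reversed
when the left gene is the higher one, and an exact tie keeps the original
orientation (deterministic no-flip). Orientation is an involution —
swapping the two FPKM values twice restores the original vector.

BDP intervals differ in length, and how unequal intervals were co-averaged
in the original metagene figures is not stated. Our choice: the two 1-kb
flanks keep their exact 20 windows of 50 bp, and each BDP segment is
linearly rescaled (interpolation between width-weighted window centres)
onto a fixed 20-window frame before the element-wise mean. The rescaling
preserves profile shape but not the conservation identity, which is why
conservation is asserted pre-rescaling.

`tss_peak_summary()` reports the density in the strand-aware window
100–150 bp downstream of a TSS — where the +1 nucleosome peak of a phased
array is expected — and `estimate_phasing_period()` reads the array period
off the first nonzero-lag maximum of the profile autocorrelation. At 50-bp
windows a 165-bp repeat is resolvable only to ±one window, so all period
assertions use that tolerance.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes and
nothing more. Its defaults are the study conditions: 290/294/627 pairs in
classes I/II/III, the observed four-category mix per class, 11 libraries,
a 165-bp nucleosome repeat, and one million mapped fragments.

* **Annotation.** Pairs and unidirectional filler genes are laid out on
  one chromosome with 2-kb bodies and 2-kb gaps, large enough that no
  unplanned divergent pair can arise and every 1-kb flank fits. Class-I
  intergenic lengths are drawn from [20, 250] rather than (0, 250]:
  below ~20 bp integer rounding makes it impossible to plant a category
  that every classifier `mid_fraction` in (0.1, 0.4) recovers
  unambiguously.
* **Peaks.** `one_mid` peaks are jittered within 8% of the BDP centre and
  `one_amesial` peaks placed within 8% of one TSS, so the planted margin
  respects every classifier threshold in (0.1, 0.4); `bi` plants two
  peaks near the quarter points. Peak widths are drawn even so the BED
  midpoint equals the planted midpoint exactly.
* **Expression.** Per pair, FPKM across libraries is bivariate lognormal.
  The target correlation is defined on the FPKM scale, so the latent
  Gaussian correlation is the exact inversion
  `rho' = log(1 + rho*(exp(s^2) - 1)) / s^2`; with the default spread
  `s = 0.8` the 11-library sample PCC averaged over pairs reproduces the
  planted value to within about 0.01. Mean log-FPKM decreases linearly
  with the planted DHS-to-TSS distance (intercept 2.2, slope −0.002/bp,
  chosen so mean FPKM runs from ≈12 near the TSS to ≈2 at 1 kb, matching
  the magnitudes the analysis operates on); no-DHS pairs use the maximum
  distance. A configurable fraction of genes (default 3%) is planted
  all-zero to exercise the FPKM = 0 filter.
* **Fragments.** Midpoints are Poisson-sampled from a deterministic
  intensity: uniform background plus, per gene, a damped train of
  Gaussian bumps (sd 20 bp, damping 0.8 per nucleosome) with dyads at
  `TSS + (k − 1/2) * 165` in the direction of transcription, and
  intensity suppressed to near zero across every planted DHS (the NDR).
  Amesial pairs receive an amplitude asymmetry (default ratio 2) toward
  the DHS-proximal gene.

Every stage is a pure function of the configuration: stage-specific seeds
are derived from the master seed, and regeneration is byte-identical.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: peak-calling noise (planted categories
are noiseless, so 100% recovery is a round-trip property, not an accuracy
claim for real peak calls), sequence composition and mappability,
overlapping or nested gene models, chromosome ends, inter-library
normalisation artefacts, and any coupling between expression and
occupancy beyond the planted distance decay and asymmetry.

## Problem sizes and runtime choices

The test suite runs the generator at 30–300 pairs with 5 × 10^4 to 10^6
fragments, sizes at which every statistical tolerance used (±0.05 on mean
PCC at 500 pairs × 11 libraries, ±0.02 on K-S type-I error at 1000
replicates, ±one window on the nucleosome period) follows from sampling
theory rather than generosity. `scripts/acceptance.R` runs the full
pipeline once at the study scale (1211 pairs, 1000 filler genes, 10^6
fragments), which completes in well under a minute.

## Known limitations

* The original contingency table depends on an unpublished centring
  threshold; with the default `mid_fraction = 0.25` the synthetic
  category mix is reproduced, but real-data category counts will shift
  with the threshold and should always be reported alongside it.
* Pearson coexpression on raw FPKM is sensitive to single extreme
  libraries; the package follows the original design rather than using a
  rank correlation.
* Metagene averaging rescales BDP intervals, so features at fixed
  distances from one TSS (rather than fixed fractions of the BDP) blur
  for long promoters.
* `run_metagene()` profiles one fragment library at a time; comparing
  multiple histone marks means one run per mark.
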