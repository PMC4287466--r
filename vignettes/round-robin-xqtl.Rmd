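---
title: "Round-robin X-QTL mapping: model and methods"
author: "rrqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Round-robin X-QTL mapping: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrqtl)
```

## The mapping problem

Bulk-segregant analysis with extremely large pools (X-QTL) maps
quantitative trait loci by comparing allele frequencies between a
*selected* pool of recombinant haploid segregants and a matched *control*
pool. A locus that affects survival or growth under the selective
condition shifts the frequency of the favorable allele in the selected
pool; everywhere else, the two pools share the same expected frequencies.
`rrqtl` implements this analysis for a *round-robin* panel: K diverse
parent strains arranged on a cycle, each crossed to its two neighbors, so
that every allele enters at least two crosses. This design supports a
second analysis unavailable to pairwise crosses: scoring every candidate
variant in a QTL region by how well its *segregation pattern* across the
crosses matches the pattern of QTL detection, which substantially narrows
the list of candidate causal variants.

Mating-type sorting plays two roles. Pools of MATa and MATalpha haploids
are isolated separately, giving an internal replicate of every selection
experiment; and subtracting MATalpha from MATa allele frequencies exposes
loci whose effect depends on the mating type itself. Chromosome 3 is
excluded from that contrast because it carries the MAT locus, which the
sorting skews to fixation by construction.

## The latent-frequency Markov model

The core statistic converts binned allele counts into per-bin LOD scores.
Counts are summed into contiguous bins of `bin_bp` = 100 bp (half-open
`[start, start + 100)` windows). Within one pool, the latent pool allele
frequency `p` along a chromosome is modeled as a hidden Markov chain on a
discrete frequency grid:

* **Transitions.** Crossing one bin corresponds to a recombination
  fraction `rho` given by the Haldane map at the genome-wide scale of
  2200 bp/cM. In a pool of `N` segregants each of which independently
  switches parental origin with probability `rho`, the frequency moves to
  a value with mean `(1 - rho) p + rho (1 - p)` and variance
  `rho (1 - rho) / N`. The kernel is discretized by evaluating the normal
  density at the grid points, truncating to `[0, 1]`, and renormalizing
  each row.
* **Emissions.** The bin's parent-A read count is Binomial(depth, `p`),
  with the exact binomial mass (no normal approximation, so low-depth
  bins are handled correctly). Bins without reads contribute no emission
  and the chain simply steps across them.
* **Prior.** Uniform over the grid at the start of each chromosome;
  chromosomes are independent (the chain restarts, as there is no linkage
  across chromosomes).

The scaled forward-backward algorithm (implemented in C++ over the banded
kernel) yields each bin's posterior distribution of the latent frequency
and the track's log-likelihood. The recursion is checked against
exhaustive enumeration of all grid paths on small instances; the two agree
to better than 1e-9 in log-likelihood.

### Grid resolution

The natural latent state space is the number of pool individuals carrying
the allele, so the default grid has `pool_size + 1` points (1001 for the
default `N` = 1000, spacing 1/N). This choice is not cosmetic: the
per-bin random-walk standard deviation is `sqrt(rho (1 - rho) / N)`
(about 6.7e-4 in frequency units at the defaults), and a grid much
coarser than that cannot represent the walk's sub-grid drift -- after
discretization the kernel collapses onto the diagonal and the chain
freezes, which destroys both the calibration of the null and the spatial
localization of peaks. A grid matched to count resolution keeps the
discretized kernel's one-step variance within a few percent of
`rho (1 - rho) / N`. `grid_size` remains configurable for small exact
test cases.

### The contrast LOD

Selected and control pools are scored independently; per bin `i`, with
posteriors `post_sel` and `post_con` over the grid of size `T`, the
posterior match `m_i = sum_p post_sel(i, p) post_con(i, p)` is compared
with the match expected under the uniform prior (`1/T`):

    LOD(i) = log10( (1/T) / m_i )

This is a Savage-Dickey style Bayes factor against the hypothesis that
the two latent frequencies are equal at that bin: matched, concentrated
posteriors give `m_i` far above `1/T` and hence negative scores (evidence
*for* equality, clipped to 0 by default, since published QTL tracks are
non-negative and peaks are what is called); divergent posteriors give
large positive LOD. The posterior match is floored at the smallest
positive double so the score stays finite even when the posteriors are
numerically disjoint. This statistic uses the same inputs and parameters
as the established pooled-contrast LOD methods and reproduces their
qualitative behavior; bit-level equality with any particular
implementation is not claimed.

## QTL calling, replication and grouping

Peaks are local maxima above LOD 5; each peak's support interval extends
outward to the first bins where the LOD drops more than 2 below the peak.
Overlapping drop intervals are merged keeping the higher peak (leftmost
on ties, for determinism), so one peak's shoulder is never reported
twice. Calls from the two mating-type selections of a cross replicate
each other when their intervals overlap; the merged call takes the mean
of the interval bounds, peak positions and LODs. When more than two
intervals fall in one overlap cluster, the mean is taken over all
members (a global rather than pairwise mean). Calls observed at two
dosages of the same stressor merge the same way, except the merged LOD is
the *minimum* across dosages -- a deliberately conservative summary.
Finally, replicated calls are grouped across crosses by single-linkage
interval overlap (the simplest closure consistent with "overlapping"
regions), and every cross, detected or not, contributes its
replicate-averaged maximum LOD inside the merged region, giving the
quantitative detection vector used by the association step. Unreplicated
calls can still be audited with `direction_agreement()`, which checks
whether the sign of the region-mean frequency contrast agrees between the
paired experiments and calibrates the observed agreement by genome-wide
permutation of the marker-level contrasts.

## Variant-segregation association

For a QTL group, `segregation_matrix()` records which crosses segregate
each region variant (parents carry different alleles), and
`association_score()` computes the squared Pearson correlation between
that indicator and the per-cross maximum-LOD vector. Zero-variance
patterns score 0 by convention -- a variant segregating everywhere or
nowhere carries no information. Significance uses an empirical null from
permutations of the cross labels of the LOD vector with an add-one
corrected p-value and alpha = 0.01. One structural limitation is worth
knowing: with 12 crosses, a variant segregating in exactly 2 of them can
match the label permutation in `2 * 10! / 12! = 1/66` of permutations, so
its p-value cannot fall below about 0.015 and the 0.01 threshold is
conservative for such patterns; ranking by r-squared is the informative
output at this panel size, and larger panels sharpen the attainable
p-values. The scorer itself is annotation-agnostic; in practice only
non-synonymous coding variants of a region are scored when annotations
are available.

## The synthetic-data generator

The simulator generates what the analysis assumes, end to end: parent
genotypes (a configurable fraction of variants private to one strain,
the rest randomly split, never monomorphic; a MAT locus at the midpoint
of chromosome 3 whose alleles track the alternating mating types of the
cycle), meioses (per chromosome, a two-state parent-of-origin Markov
chain with Haldane switch probabilities -- consistent with the
no-interference assumption of the LOD model's transition kernel),
mating-type sorting (a hard filter, matching FACS), viability selection
(soft, exponential weighting `w = exp(sum beta)` with resampling
proportional to `w`, matching growth competition), and pooled sequencing
(Poisson depth around a mean of 50x, binomial read sampling, and
copy-number regions as pure depth multipliers -- matching the
coverage-ratio estimator used for copy-number calls).

Default conditions mirror the experiment the package models: 12 parent
strains, pools of `N` = 1000 segregants (the pool size the LOD model
assumes), 50x depth, one marker per ~500 bp, 2200 bp/cM. Where the
calibration and power analyses need a long uniform chromosome they use a
single 1 Mb chromosome with 2000 markers; that size keeps a full
20-replicate calibration run in the low minutes on one CPU while still
spanning several Morgans of map.

What the generator does *not* emulate: diploid intermediates, aneuploidy,
de novo mutation, sequencing error beyond binomial sampling, read-level
artifacts (mapping bias, duplicates), segregation distortion unrelated to
the planted effects, and linkage disequilibrium structure among parent
genomes (alleles are assigned independently across markers). Passing
tests on these simulations therefore validate the statistical machinery
-- calibration of the null, localization of planted effects, correctness
of the recursions -- not robustness to alignment artifacts or to
model misspecification in real sequencing data.

### Calibration and power, as implemented

The null calibration simulates one unselected pool and sequences it twice
independently -- the analog of technical replicate libraries from one
sorted population, which is the setting in which replicate experiments
are expected to show no LOD excursions at all. Across 20 such pairs the
genome-wide maximum LOD stays below 5 (in practice, the clipped tracks
are flat at 0), and no replicated QTL are called. Two *biologically*
distinct pools of 1000 segregants, by contrast, genuinely differ by
resampling noise of order 1-2% in allele frequency, and very deep
sequencing can make that difference significant; that is a property of
the experiment, not a miscalibration of the statistic. The power
analysis plants a single viability locus with an expected post-selection
frequency shift of 0.2 (`beta = ln(7/3)` from a pre-selection frequency
of 1/2) and requires the peak within 30 kb of the truth with the 2-LOD
interval covering it.

## Numerical choices

* Marker coordinates are 1-based inclusive; bins are half-open
  `[start, start + r)`; BED/bedGraph outputs convert to 0-based half-open
  on write and back on read.
* The forward-backward pass is scaled per step; posteriors are
  renormalized exactly per bin (columns sum to 1 within 1e-12).
* Ties between equal-LOD bins resolve to the leftmost bin.
* The truncated-normal kernel row-renormalizes after truncation at the
  `[0, 1]` boundary; if an entire row underflows (possible only for
  extreme `rho` with enormous `N`), the row degenerates to a point mass
  at the nearest grid point.
* `min_depth` for frequency tracks defaults to 10: below that the
  count ratio is too noisy to be useful and 0/0 is undefined. The LOD
  model consumes raw counts and needs no such filter.
* Moving-average smoothing (`smooth_track`) is provided for display; it
  is deterministic and windowed in base pairs, and is never used in the
  LOD computation. Boundary windows are truncated, so the smoothed track
  mean is exactly preserved only for constant tracks.
* `derive_seed()` gives every pool/cross/stage its own reproducible
  sub-seed from one top-level seed, so whole runs are reproducible while
  stages stay independently re-runnable.

## Known limitations

* The LOD statistic is pointwise; it does not pool evidence across more
  than two pools, and interval estimation is entirely the caller's
  2-LOD-drop construction.
* The association step assumes additive, background-independent variant
  effects; context-dependent QTL (detected in one cross only) violate
  that assumption by definition and are flagged by low detection counts
  rather than explained.
* Selection is modeled on single markers; planted effects must coincide
  with a marker position.
* With an odd number of strains a cyclic design cannot alternate mating
  types consistently; the constructor warns and the simulator should be
  used with even panels.
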