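---
title: "Comparative copy-number and allelic-imbalance analysis with cghcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative copy-number and allelic-imbalance analysis with cghcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cghcohort)
```

## The analysis this package implements

`cghcohort` reimplements, as reusable and tested functions, a comparative
genomics workflow for two tumor cohorts — typically metastases versus
primary tumors — profiled on three platforms:

1. **Array CGH**: per-sample log2 tumor/reference ratios on a shared probe
   grid are turned into per-probe copy-number calls
   (loss / normal / gain / high-level amplification), then the two cohorts
   are compared probe by probe and significant probes are merged into
   reportable genomic regions.
2. **Microsatellite allelotyping**: tumor/normal allele peak heights at a
   marker panel are turned into allelic-imbalance (AI) calls per marker,
   per-sample region statuses, and cohort-level "core regions" where AI
   concentrates.
3. **Expression microarrays**: a SAM-style permutation test finds
   differentially expressed genes between the groups, and a positional
   filter narrows them to abundant, strongly changed transcripts in a
   region of interest (chromosome 10q in the motivating design).

A synthetic-cohort generator with planted ground truth accompanies every
stage, so the full pipeline is testable end to end without any external
data.

## Copy-number calling model

Each sample's profile is processed as: median centering → per-chromosome
piecewise-constant segmentation → threshold calling → recentering on
normal segments → a second segmentation and calling pass.

**Centering.** Log2 ratios are centered to a median of zero. A whole-genome
median is biased when a large fraction of the genome is aberrant, which is
why a second pass recenters using only probes inside segments called
*normal* in the first pass and repeats segmentation. On profiles where a
quarter of the genome is lost, the test suite shows the second pass
raising per-probe call accuracy from roughly 0.7 to above 0.99; on mostly
balanced genomes the two passes agree.

**Segmentation.** The segmentation contract is what downstream calling
relies on: contiguous, non-overlapping per-chromosome segments covering
all non-missing probes, each probe assigned its segment's arithmetic mean.
The engine is recursive binary splitting minimizing within-segment sum of
squares. A split is accepted only when the sum-of-squares drop exceeds a
penalty of `4 * sigma^2 * log(n)` (per chromosome, `sigma` estimated as
`mad(diff(x))/sqrt(2)`), and no segment may be shorter than
`min_seg_probes` (default 5). The factor 4 reflects that the split
statistic is maximized over all split points, so the null drop
concentrates well above the single-split chi-square scale; a planted
single-copy change of 0.5 log2 units across even five probes yields a
drop an order of magnitude above this penalty at realistic noise. On
noiseless profiles with at most two changepoints the result provably
coincides with exhaustive least-squares search, and the suite verifies
this equivalence on random small cases.

**Thresholds.** Segment means strictly above +0.05 are gains, strictly
below −0.05 losses; means at or above 1.0 log2 are reported as high-level
amplifications. The ±0.05 defaults follow the convention of calibrating
cutoffs on the residual spread of X/Y probes in sex-mismatched
hybridizations, where a true single-copy offset is known by design;
`derive_thresholds()` exposes the multiplier `k` (cutoff = `k` × residual
SD) rather than hard-coding the mapping, because no canonical value for
`k` exists. Ties at exactly ±0.05 are *normal*: the inequalities are
strict. The amplification cutoff of 1.0 log2 is conventional aCGH
practice; it is configurable because reported high-level amplification
thresholds vary between laboratories. Sex chromosomes are excluded from
all downstream cohort statistics, since a sex mismatch makes them
uninterpretable for tumor copy number.

**Missing probes** are excluded from medians, segment means and calls, and
propagate as missing calls; frequency denominators shrink accordingly.

## Cohort comparison

Per probe and group, the gain frequency is the percentage of samples
called gain *or* high-amplification, and likewise for losses. The
between-group test is the two-sided Wilcoxon rank-sum test applied to the
*segmented* values (each sample contributes its assigned segment mean, the
same data the calls are made from). The exact distribution is used when
the combined sample size is at most 20 and there are no ties; otherwise
the normal approximation with tie correction (and without continuity
correction) is used. Raw p-values are adjusted with Benjamini–Hochberg's
step-up procedure.

Regions are maximal runs of consecutive same-chromosome probes with
`p < 0.05` **and** `FDR < 0.04` (both configurable). Each region reports
the min–max range of every group's gain/loss frequencies and of p/FDR over
its probes, because cohort tables conventionally print ranges; sizes in
Mbp are `(end − start)/1e6` rounded **half-up** to one decimal (base R's
round-half-even would print 10.25 Mbp as 10.2 rather than the conventional
10.3). The same half-up rule applies to all printed-style percentages.

A separate screen, `high_freq_difference_loci()`, reports contiguous runs
where the two groups' frequencies differ by more than 30 percentage points
(per direction), the conventional "large frequency difference" summary. A
"locus" here is a merged contiguous probe run; coarser granularities are
defensible but this one is self-consistent with the region logic.

**Power honesty.** At 20 + 20 samples and 2000 probes, a prevalence
contrast of about 75% vs 5% puts region probes comfortably below the
FDR 0.04 line, but a 70% vs 20% contrast does *not*: its idealized
rank-sum p (~0.01) cannot clear genome-wide BH correction at these ranks.
The default simulated cohort therefore plants contrasts in the strong
range, which is also where the motivating study's reported regions sit
(60–90% versus 0–13%). Boundary probes of a true region sit close to the
FDR cutoff by construction, so recovered region edges can wobble by a few
probes between seeds.

## Allelic imbalance from peak heights

For a normal-tissue-heterozygous marker, the tumor allele ratio is
normalized by the constitutive ratio and folded to at least one:

> fold = max(r, 1/r),  r = (hT1/hT2) / (hN1/hN2)

A fold of **2.0 or higher** is AI (the boundary is inclusive); below, the
marker is retained. Homozygous normals are noninformative; absent tumor
data is missing; a heterozygous normal whose tumor shows one allele is
complete loss (AI, infinite fold). Normalizing by the constitutive ratio
is standard LOH practice — it cancels constitutive amplification skew —
but because source descriptions of "tumor/normal peak-height ratio" are
often ambiguous on this point, the unnormalized variant is available via
`normalized = FALSE` for sensitivity analysis.

Under the purity model (a fraction *f* of tumor cells lost one allele, so
the lost allele's expected height scales by 1 − *f*), the noise-free fold
is 1/(1 − *f*): AI is called exactly when *f* ≥ 0.5. With multiplicative
log-normal peak noise at CV 0.1 and *f* = 0.7 the caller is better than
99% sensitive with essentially no false AI calls, as the suite and the
acceptance script verify on 200-sample simulations.

A sample's region status is AI if *any* informative marker in the region
shows AI, normal if it has informative markers and none shows AI, and
noninformative otherwise. Group frequency tables report carriers over the
full group size (the convention of clinical frequency tables), rounded
half-up to one decimal, and always recompute exactly from the emitted
counts.

**Core regions** are maximal contiguous marker runs whose AI frequencies
(computed over informative samples only) all reach `min_freq = 0.3` and
that are local maxima: each flanking marker must sit at least
`min_prominence = 0.15` below the run's peak frequency. A run spanning the
whole panel has no flanks and is not a hotspot — uniform AI is a whole-arm
event, not a core region. The 0.3/0.15 defaults are this package's
choices: published core regions are described, not derived, so any
detector needs explicit parameters; these values separate hotspot markers
(≈40–50% AI) from whole-arm background (≈10–20%) in the default
simulation with a wide margin.

## Association statistics

AI-by-group tables are tested with the two-sided Fisher exact test in the
point-probability convention (sum of all margin-compatible tables whose
hypergeometric probability does not exceed the observed one, with a 1e-7
relative tie tolerance guarding against floating-point inclusion errors),
and with Pearson's chi-squared test (Yates correction optional, off by
default). Published two-sided Fisher p-values do not always state their
convention; on one published carrier table this convention yields 0.0083
where 0.003 was printed, and the package reports its own convention
rather than matching opaque values. Noninformative samples are excluded
from association tables.

## SAM-style differential expression

Samples are quantile normalized (every sample receives the cross-sample
rank-mean distribution; ties get the mean of implicated rank means). The
per-gene statistic is `d = (mean2 − mean1)/(s + s0)` with `s` the pooled
standard error of the difference and `s0` a fudge factor that stabilizes
low-variance genes; `s0` defaults to the 5th percentile of the per-gene
`s` distribution, a common simplification of SAM's coefficient-of-
variation tuner, and is configurable. The null distribution comes from
seeded unpaired label permutations (200 by default; all distinct
permutations if fewer exist). For each candidate cutoff (the observed
|d| values), the estimated FDR is the median permuted count of |d| at or
above the cutoff divided by the observed count; the significant set is
the largest with estimated FDR at or below the target (5% default), and
per-gene q-values are the monotonized estimates.

Under the complete null this estimator occasionally declares a single top
gene (the median permuted count at the top cutoff is 0 in about half of
runs, by exchangeability of the observed and permuted maxima) — a known
property of median-based permutation FDR, not an implementation artifact.
Across 20 null simulations of 2000 genes the mean fraction of genes
declared stays below 2.5 in 10,000, far under the nominal rate.

Candidate filtering keeps significant genes that are (a) at or above the
25th percentile of overall expression, interpreted as the percentile of
per-gene mean expression across all samples, (b) on the configured
chromosome (optionally inside a closed bp window), and (c) changed more
than 2-fold, with the fold change computed on anti-logged group means and
the cut applied two-sidedly. `genes_in_region()` intersects candidates
with closed bp intervals.

## What the generators emulate — and what they do not

The aCGH generator plants interval aberrations with group-specific
prevalences; a carrier's probes shift by the aberration effect, plus
independent Gaussian probe noise (`noise_sd = 0.15`, a typical
oligo-array spread) and a per-sample baseline error
(`baseline_shift_sd = 0.05`) that the two-pass centering must remove. The
default cohort is 20 metastases vs 20 primaries on 2000 autosomal probes
laid out proportionally to chromosome lengths, with three strongly
group-differential aberrations (7p gain, 10q loss, 17q loss, effects
±0.5) and two shared ones (8q gain, 16q loss) of nearly equal prevalence.
The sex-mismatch generator places configured X/Y offsets (defaults +1/−1
log2) over the same noise model.

The microsatellite generator draws per-marker heterozygosity (0.7),
applies the purity model with loss fractions sampled from {0.7, 0.9}
(emulating macrodissected samples with at least 70% tumor-cell content)
and multiplicative log-normal peak noise (CV 0.1, mean exactly 1). Its
default panel is eleven synthetic markers across 10q22.3–qter with a
low-prevalence whole-arm AI background plus two core regions, CR1 over
the PTEN locus markers and CR2 distally, both enriched in the metastasis
and brain-relapse groups. Marker names follow D10S nomenclature but
positions are synthetic. The four group sizes (21/39/10/17) mirror the
motivating cohort; the planted per-group prevalences favor robust
core-region detection over exact reproduction of published marginal
percentages, which would place cohort core frequencies almost exactly at
the detector's 0.3 floor.

The expression generator draws per-gene baselines from N(7, 2) log2
units with measurement noise SD 0.5 and shifts 50 genes on 10q by −1.5
log2 in the metastasis group (10 vs 10 samples).

None of the generators simulate raw images, dye effects, GC waves,
spatial artifacts, stutter peaks or probe-specific biases; noise is
independent across probes. Passing recovery tests therefore demonstrates
the correctness of the algorithms under the stated statistical model, not
robustness to every artifact of real arrays. Real-data preprocessing
(spot filtering, dye normalization, CEL processing) is out of scope and
assumed done upstream.

## Numerical choices and degenerate inputs

* Rounding of printed-style quantities: half-up, one decimal.
* Segmentation split acceptance uses a 1e-10 absolute guard so that
  zero-noise profiles never split on floating-point dust; ties among
  equally good splits resolve to the leftmost.
* A profile with no normal-called segments skips recentering with a
  warning; an all-missing profile, an empty probe panel, a zero-variance
  X/Y reference, nonpositive peak heights, non-integer contingency
  counts, and p-values outside [0, 1] are rejected with explanatory
  errors. Peak-table records with nonpositive heights are dropped with a
  warning rather than poisoning the table.
* Probes with zero variance in both groups get p = 1; all-zero rows or
  columns are dropped (with a warning) before chi-squared testing.
* Coordinates are 1-based inclusive bp throughout; all intervals are
  closed.

## Problem sizes used by the test suite

The suite exercises the full default cohorts: 2000 probes × 40 samples
for copy number, 11 markers × 87 samples (plus a 200-sample single-marker
purity simulation) for AI, and 2000 genes × 20 samples with 200
permutations (plus twenty 2000-gene null simulations) for expression.
Statistical primitives are checked against enumeration oracles on
thousands of random small cases. The whole suite runs in well under a
minute on a single core.

## Known limitations

* Binary segmentation is greedy; pathological configurations of three or
  more closely spaced changepoints can be merged or shifted relative to
  the global optimum. The contract deliberately permits swapping in any
  engine that meets the piecewise-means postconditions.
* Region boundaries inherit the knife-edge behavior of thresholded BH
  masks; a boundary probe's FDR near 0.04 can move edges by a few probes
  between seeds.
* The median-based permutation FDR can admit one spurious gene under the
  complete null, as discussed above.
* Cytogenetic band labels are passed through from user-supplied tables,
  never computed.
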