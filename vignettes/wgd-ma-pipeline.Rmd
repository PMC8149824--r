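---
title: "Calling WGD, aneuploidy, LOH and growth rates in yeast mutation-accumulation lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling WGD, aneuploidy, LOH and growth rates in yeast mutation-accumulation lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdma)
library(dplyr)
```

## The experimental design this package analyses

Mutation-accumulation (MA) experiments propagate many independent yeast
lines through repeated single-colony bottlenecks, so that selection is
minimised and spontaneous genomic changes accumulate near-neutrally. In the
design `wgdma` targets, each cross between two parental strains (within a
*S. paradoxus* lineage, between lineages, or between species) is founded
48–96 times independently and carried through 35 passages — roughly 770
generations at ~22 generations per passage. Along the way, four kinds of
measurements are taken, and `wgdma` implements the computational analysis of
each:

1. **Ploidy from flow cytometry.** Per-cell DNA-content fluorescence
   (~5000 cells per sample) yields G1 and G2 population peaks; the G1 peak
   position is proportional to ploidy. Spontaneous whole-genome duplication
   (WGD, diploid → tetraploid) appears as a doubling of the G1 peak.
2. **Chromosome copy number from sequencing depth.** Read depth averaged in
   10-kb windows, normalised by genome-wide coverage; the per-chromosome
   median ratio times the baseline ploidy is the chromosome copy number,
   and the difference between the final and initial timepoints gives
   chromosome gains and losses (aneuploidy).
3. **Loss of heterozygosity (LOH) from allele frequencies.** In hybrid
   lines every heterozygous site is parent-informative; runs of markers
   whose parental allele frequency departs from the chromosome average mark
   tracts where one parent's haplotype was lost.
4. **Maximum growth rate from OD curves.** OD600 read every 15 minutes; the
   growth rate is the 98th percentile of slopes of linear regressions in
   10-timepoint sliding windows.

A fifth module simulates all four data types with known ground truth, so
that every stage can be validated by parameter recovery without any
deposited data.

## Ploidy calling

The per-cell fluorescence distribution is summarised by a Gaussian kernel
density estimate (`stats::density`); its local maxima are candidate peaks.

* **Bandwidth.** Silverman's rule of thumb (`bw.nrd0`) by default,
  overridable. No estimator is canonical for this assay; Silverman is the
  standard default and resolves G1/G2 peaks separated by a factor of two at
  coefficients of variation up to ~8%.
* **Peak prominence.** Peaks below 5% of the maximum density are discarded.
  This rejects debris shoulders (sub-G1 events) without touching the G2
  peak, whose height is roughly a third to a half of G1 in a cycling
  culture.
* **G1/G2 assignment.** Of the two highest peaks, the lower *position* is
  G1. A sanity band requires G2/G1 ∈ [1.6, 2.4] (the theoretical ratio is
  2); outside it, or when only one peak is found, the call falls back to
  the single dominant peak and is flagged `warn` instead of being dropped —
  a trajectory with a warned point is still usable for WGD detection.
* **Calibration.** The fluorescence-per-haploid-genome unit is the
  least-squares slope through the origin of G1 peak position against known
  control ploidy, \(\hat u = \sum_i p_i g_i / \sum_i p_i^2\), over parental
  strains measured in haploid and diploid state. Controls failing their own
  G2/G1 band are excluded.
* **Classing.** `ploidy = g1_peak / unit` is continuous. It is rounded to
  the nearest integer class when within 0.15 of it, and reported
  `"fractional"` otherwise. The band must be narrow enough that genuinely
  non-integer states (tetraploids decaying through ~2.8n by serial
  chromosome loss) are *not* rounded to 3n; 0.15 leaves those fractional
  while integer ploidies at realistic noise (CV 5%, 5000 cells) are still
  classified essentially perfectly.

**WGD events.** A line records an event at the first timepoint whose class
is at least twice its baseline — the class at its own first observation, so
triploid-founded lines (frequent in crosses where one parent spontaneously
diploidised) are judged against 3n. One tetraploid observation suffices;
later returns below twice the baseline (integer or fractional) annotate the
event `reverted` rather than erasing it, because transient tetraploidy is a
real observed behaviour, not noise.

**Rates.** The per-cross WGD rate divides event lines by the founding lines
of the cross (extinct lines stay in the denominator). The printed rates in
the literature are not always reconstructible to one denominator
convention, so a `"surviving"` policy is also implemented and exposed as an
argument; the founding policy is the default because extinction is itself
an outcome of the propagation regime, not a reason to shrink the exposure
set.

## Copy number and aneuploidy

Per-base depth is averaged over 10-kb tiling windows (final window
shorter). When a chromosome-length table is supplied, unreported positions
count as depth zero; otherwise means are over observed positions only and
flagged. Window means are divided by the genome-wide coverage, defined as
the mean over all window means — the natural reading of "whole-genome
coverage" on binned data. The chromosome copy number is
`round(median(ratios) * baseline_ploidy)`.

Numerical choices:

* A **no-call band**: when the scaled median's fractional part falls in
  [0.35, 0.65] the call is flagged `warn`. Rounding alone would silently
  turn mosaic or noisy chromosomes into confident integer calls.
* An optional **mask** excludes windows (e.g. the rDNA array on chromosome
  XII, a tandem repeat whose copy number varies independently of the
  chromosome) from the median.
* A **consensus rule** over per-window integer calls (for consumers of
  window-level callers): modal value, ties broken toward the baseline
  ploidy, then toward the smaller value — deletions are the more
  conservative call when evidence is balanced.

Aneuploidy per line is counted at the final timepoint against the line's
ploidy class *at that timepoint*, so a tetraploid line with a trisomic-like
chromosome at 3 copies counts one aneuploidy. Gain/loss spectra report the
fraction of lines gaining or losing each chromosome.

## LOH segmentation

Markers are Freebayes SNPs passing: QUAL > 1, QUAL/AO > 10, SAF > 0,
SAR > 0, RPR > 1, RPL > 1, 0.9 < MQM/MQMR < 1.05; indels, multiallelic
records and repeat-overlapping records are excluded. The parental allele
frequency is `depth_a / total_depth`, keeping only markers with total depth
strictly above 20 reads. The chromosome baseline is the arithmetic mean
allele frequency over all retained markers, computed *before* any candidate
exclusion.

Segmentation applies three rules:

1. candidates deviate from the chromosome baseline by more than 0.15;
2. a segment needs at least three successive candidate markers with the
   same allele frequency within ±0.1;
3. consecutive member markers may be at most `max_gap` apart — 300 bp for
   hybrid crosses, 1 kb for low-heterozygosity intra-lineage crosses.

Two readings of the published rules were genuinely open and are fixed here
as package decisions, both exposed as arguments:

* the 300 bp / 1 kb "window" bounds the spacing between *consecutive member
  SNPs*, not the total run span — the span reading would forbid the
  multi-kilobase segments that demonstrably exist;
* "same allele frequency (±0.1)" is evaluated against the *running mean* of
  the current run, which tolerates binomial read-sampling noise around a
  common level while stopping slow drift; comparing only adjacent pairs
  would let a run drift arbitrarily far.

Runs are built greedily left to right; a non-candidate marker, an over-long
gap, or an allele-frequency break closes the run, which is emitted if it
has ≥ 3 members. Segment size is `end − start` over member SNP positions. A
segment containing the chromosome's first or last retained marker is
`terminal`, otherwise `interstitial` (the published analysis distinguishes
the kinds without defining them; touching a chromosome-end marker is the
operational reading). Cross-level comparisons use only segments larger than
1 kb, because the coarser 1-kb gap rule in sparse crosses cannot produce
smaller ones — counting them elsewhere would bias any between-cross
contrast.

Chromosomes whose marker density falls below 1 per 10 kb are refused with
an informative error rather than segmented: with so few markers the
three-SNP rule spans tens of kilobases and the baseline itself is
unreliable. In triploid hybrids (baseline 1/3 or 2/3) segmentation is
unchanged and each segment is annotated with which parental allele class
was lost, from the sign and magnitude (in units of 1/3) of the allele
frequency shift. In tetraploids the diploid baseline of 0.5 applies
unchanged, with the documented caveat that recombination between identical
homologues is invisible to parent-informative markers, so tetraploid LOH
rates are lower bounds.

## Growth rates

Slopes are fitted by ordinary least squares in 10-timepoint sliding windows
(2.25 h at 15-min readings) and the rate is the 98th percentile of the
slope set, with linear interpolation between closest ranks
(`stats::quantile` type 7, fixed for bit-stability). Regression is on
natural-log OD by default — the slope of log OD in exponential phase *is*
the per-hour growth rate, and it makes the estimate invariant to
multiplicative OD calibration. A linear-OD mode is kept for the literal
reading of the published method, which does not state the scale.

The 98th percentile rather than the maximum discounts the most
noise-inflated window. Two properties matter in practice:

* On exact exponential input the estimate equals the true rate to machine
  precision (every window has the same slope).
* On logistic curves the early-phase slope is depressed by the factor
  \(1 - OD/K\); with the assay's working inoculum (OD ≈ 0.1, saturation
  ~1.5) the estimator reads the realised early-phase rate, about 10% below
  the intrinsic rate. This is a property of the growth model, not a defect
  of the estimator, and the recovery studies therefore plant curves with a
  smaller inoculum (OD 0.05 and below, a 1:30 dilution, also common
  practice) so a genuine exponential phase spans several windows.

Fitness changes are simple differences of rates (after − before), divided
by the number of generations evolved after the event when the
per-generation convention is requested.

## Statistics

Per-cross rate comparisons use a Kruskal–Wallis omnibus plus unadjusted
pairwise two-sided Mann–Whitney–Wilcoxon tests; pairwise results are
reported regardless of the omnibus outcome, matching how such figures are
annotated. No multiple-testing correction is applied — published figure
captions report raw pairwise p-values and use a display threshold, which is
presentation, not inference. Before/after designs (fertility, fitness) use
a two-sided paired t-test; an all-zero difference vector is reported
explicitly as no-change with an undefined statistic rather than a
fabricated p-value. Exact small-sample Wilcoxon distributions are used when
the implementation supports them (no ties, n < 50), midrank normal
approximation otherwise.

## The synthetic cohort generator

The generator (`sim_config()` and the `sim_*()` functions) emulates the
study conditions: 96 lines per cross, 35 passages (~22 generations each),
per-passage WGD/reversion/extinction hazards, 5000-cell fluorescence
samples at 100 a.u. per haploid genome with CV 5%, 63% G1 / 35% G2 / 2%
debris, 90× coverage in 10-kb windows, heterozygous marker tracks at ~5
markers/kb, and logistic OD600 curves read every 15 min from an inoculum of
0.1. The default WGD hazard of 0.003 per passage yields a ~10% cumulative
WGD fraction over the experiment, the upper end of observed per-cross
rates.

Where the real experiment reports no noise model, the generator's choices
are explicit stand-ins:

* fluorescence peaks are Gaussian with a common CV; debris is uniform
  sub-G1; mixture counts are deterministic so weights are exact;
* window mean depths are Gamma with CV `coverage_dispersion` (default
  0.1) — an overdispersed-count proxy whose mean is exact and which
  degenerates to the expectation as dispersion → 0;
* marker read counts are binomial at the local target allele frequency with
  Poisson total depth;
* OD noise is additive Gaussian (default SD 0.003, typical plate-reader
  repeatability).

What the simulator does **not** emulate — and what passing recovery tests
therefore cannot certify on real data: instrument-specific fluorescence
nonlinearity and gating artefacts, mappability/GC structure in depth
(masks exist for the worst offender, the rDNA array), linked marker noise
from alignment errors around structural variation, diauxic shifts or lags
in growth curves, and any selection during propagation.

## Validation scales

The test suite validates each stage at fixed problem sizes chosen to give
tight Monte-Carlo bounds while keeping the default run fast: 1000 random
marker tracks (≤ 50 markers) against a brute-force segmentation oracle;
100 planted LOH tracts of 1–5 kb at 6 markers/kb and depth 40 (≥ 95%
breakpoint-exact recovery) plus 1000 null tracks at depth 30 (< 1% false
discovery); 200 fluorescence replicates at each ploidy 1–4 (≥ 99% correct
classification) and a 96-line cohort with every planted WGD passage
recovered on the observation grid; ~1000 simulated chromosomes at 90×
coverage with exact copy-number recovery in ≥ 99% and exact invariance
under depth scaling; 100 noisy logistic curves with the planted rate
recovered within 5% in the median; and 200 seeded cohorts per hazard
checking the simulated WGD fraction against the closed form
\(1 - (1 - h)^{35}\) within three standard errors.

## Known limitations

* Sub-chromosomal CNV segmentation, breakpoints and GC correction are out
  of scope; copy number is whole-chromosome only.
* The LOH gap rule splits very long tracts whenever marker spacing locally
  exceeds `max_gap`; at moderate densities a 50-kb tract is usually
  reported as several abutting segments rather than one.
* Tetraploid LOH rates are underestimates (homologue–homologue events are
  invisible), and triploid baselines assume a uniform 2:1 parental ratio
  per chromosome.
* The growth-rate estimator reads the realised early-phase rate; at high
  inoculum-to-capacity ratios this sits below the intrinsic logistic rate.
* Flow calling assumes a dominant G1/G2 structure; heavily aggregated or
  arrested cultures violate it and surface as `warn` flags, not errors.
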