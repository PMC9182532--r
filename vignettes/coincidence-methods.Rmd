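---
title: "Methods: coincidence spectroscopy analysis and protected-core mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coincidence spectroscopy analysis and protected-core mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coinspec)
```

This vignette documents the models, parameter choices and numerical
conventions behind `coinspec`, and states what the synthetic-data tests
do and do not demonstrate about real instrument data.

## The measurement model

Confocal coincidence spectroscopy records photon counts from a ~1 fL
confocal volume in two spectral channels (here called *green* and *red*),
binned at 1 ms over records of minutes. Three signal sources are
distinguished:

* **monomer background** — freely diffusing labelled monomer is so
  numerous and dim that it contributes a stationary Poisson baseline;
* **homomeric assemblies** — large complexes carrying many copies of one
  label produce bright transient bursts in one channel;
* **heteromeric assemblies** — complexes carrying both labels produce
  coincident bursts in both channels.

The degree of hetero-assembly is quantified by the directional
statistic

$$\mathrm{colourQ} = \frac{\#\{\text{Colour A peaks aligned with Colour B peaks}\}}{\#\{\text{Colour A peaks}\}}$$

with RedQ = colourQ(green, red) and GreenQ the converse. colourQ counts
*distinct* A peaks: an A peak overlapping several B peaks enters the
numerator once.

## Trace simulation

`simulate_trace()` realises this model directly. Each species generates
burst events as a homogeneous Poisson process at `arrival_rate` events/s;
apex bins are uniform over the record. Each event adds a Gaussian
intensity envelope with apex amplitude `brightness` (photons/ms) and
standard deviation `transit_ms / 4`, truncated at ±3 sd. Per-bin counts
are independent Poisson draws around (background + envelope sum) ×
bin width — photon shot noise — realised independently per channel, since
the channels are physically separate detectors behind separate filters.
A dual-labelled species writes its envelope into both channels at a
common apex bin, so only the *positions* coincide, not the noise.

Numerical conventions:

* **Envelope shape.** Diffusive transits have no canonical intensity
  profile; a truncated Gaussian is smooth, two-parameter, and reproduces
  the one-to-few-bin bursts seen at millisecond binning with ~1 ms
  transits. The sd = transit/4 convention makes ±2 sd of the envelope
  span one transit time.
* **Boundary handling.** An event whose ±3 sd envelope would cross a
  record boundary is re-drawn, so the ground-truth burst count is exact
  and no partial envelopes bias edge bins.
* **Determinism.** Each simulation call consumes a single RNG stream
  seeded from its config; identical inputs give bit-identical traces.
  The caller's RNG state is preserved.

Defaults (`trace_config()`): 180 s records, 1 ms bins, background
1 photon/ms per channel — a typical dilute-monomer count rate at the
~0.2 µM concentrations used for such measurements. The mixture wrapper
(`simulate_mixture()`) uses apex brightness 120 photons/ms and 1 ms
transits, placing bursts two orders of magnitude above baseline, as large
amyloid assemblies are. With `f` the heteromer fraction and `N` the total
event target, rates split as dual : green-only : red-only =
`fN/(2-f) : (1-f)N/(2-f) : (1-f)N/(2-f)`, so the dual species carries
fraction `f` of the green-visible (and of the red-visible) events — the
quantity RedQ estimates.

**What the generator does not emulate:** optics (point-spread function,
focal-volume geometry), triplet blinking, FRET, detector afterpulsing,
dead time and spectral crosstalk, non-uniform transit paths, and
photobleaching. Passing recovery tests on these synthetic traces shows
the *analysis chain* is correct and unbiased under its own model
assumptions; it does not calibrate the method against a particular
instrument.

## Burst detection

`detect_peaks()` thresholds at `baseline + k_sigma * sigma` with

* `baseline` = median count per bin — robust to a burst-heavy upper
  tail, unlike the mean;
* `sigma` = max(scaled median absolute deviation,
  `sqrt(max(baseline, 1))`). The MAD term adapts to over-dispersed
  baselines; the square-root floor is the Poisson shot-noise standard
  deviation implied by the baseline, and guards the degenerate case of a
  (near-)constant series whose MAD is 0. Note that for discrete Poisson
  counts at moderate rates the scaled MAD sits somewhat *above*
  `sqrt(lambda)` (e.g. 2.97 vs 2.24 at rate 5), a known discreteness
  effect; the threshold is therefore slightly conservative.

A peak is a maximal supra-threshold run, after merging runs separated by
at most `merge_gap_bins` sub-threshold bins (default 0 — the simplest
reading of a "deflection from baseline"; merging is exposed for
instruments whose bursts flicker) and discarding runs narrower than
`min_width_bins` (default 1). `k_sigma = 5` by default: standard
burst-search practice, putting chance crossings of a 1-ms Poisson
background in the 10^-7 per-bin range. Apex ties inside a run resolve to
the earliest bin. Integrated photons subtract the baseline over the span
(burst photons, not total photons) and are floored at 0.

Raising `k_sigma` always shrinks the supra-threshold region and every
peak found at a higher threshold nests inside one found at a lower
threshold; the peak *count* itself can occasionally increase when a
stricter threshold splits a plateau into two runs — an intrinsic feature
of run-based detection.

## Alignment and colourQ

Two peaks are *aligned* when their spans, each dilated by
`tolerance_bins` (default 0), intersect. Span overlap rather than apex
distance is used because bursts are extended objects; an apex criterion
is recovered by degenerate one-bin spans. The dilation default of 0
reflects the 1 ms binning: a genuinely co-diffusing complex produces
bursts in the *same* bins. `chance_coincidence()` reports the analytic
chance-aligned fraction `1 - exp(-n_B (w_B + 2 tol) / n_bins)` under a
uniform-independence null; it is a diagnostic printed next to colourQ
and never subtracted from it.

For multi-record experiments, colourQ should be pooled over records as a
count ratio (total aligned A peaks / total A peaks), not averaged
per-record: averaging would weight a sparse record as heavily as a rich
one. `scripts/acceptance.R` pools this way. With zero A peaks the
statistic is undefined and reported as `NA`, never silently 0.

## Photon-counting histograms

`build_pch()` histograms peak apex intensity (photons/ms) into half-open
bins `[edge, edge + width)`; the apex statistic matches the natural
photons/ms axis of such histograms, with integrated photons available
via `statistic = "integrated"`. Default width 100 photons/ms resolves
the 0–2000 photons/ms range over which complex-size differences appear.
`compare_pch()` reports the two descriptive comparisons used in
practice: the shift of the intensity-weighted mean (bin midpoints) and
the change in tail mass above a stated intensity (default
1500 photons/ms, the regime of very large heteromeric complexes). No
Chen/Gratton-style PCH model is fitted.

## Protected-core mapping

Residue coordinates are 1-based and inclusive, numbered on the
full-length protein via the construct `offset` (the bundled construct
spans 601–712, so residue names like S654 or Q709 read directly).
`map_read()` requires an exact, *unique* substring match — overlapping
self-repeats are detected — and classifies failures as unmapped or
ambiguous; both are excluded from the profile and logged, rather than
fractionally assigned, a conservative choice that keeps prevalence an
honest read fraction. Methionine-oxidation annotations (the only
modification expected, an electrospray artefact) are stripped before
matching; the CSV dialect is `pos:ox` tokens, or inline `M[ox]`.

Prevalence at position p = (weighted reads covering p) / (weighted
mapped reads). Weighting by spectral `count` is the default ("reads"
implies read-level weighting); `weight = "unique"` gives the
unique-peptide variant, since either convention is found in practice.
`delineate_core()` returns the maximal contiguous run with prevalence ≥
threshold (default 0.7) that contains the core tetrad; the tetrad anchor
prevents an unrelated high-coverage island from being reported as the
core.

## Synthetic digests

`simulate_digest()` emits reads that are exact substrings of the parent,
each containing the tetrad (mirroring the observation that the core
motif appears in every detected sequence). Exactly
`round(core_prevalence * n_reads)` reads span the full core — a
stratified split, chosen over per-read Bernoulli draws so that the
realised core prevalence is exact rather than binomially scattered
around the target — extended past each core boundary by geometric flanks
(`P(ext ≥ k) = (1 - decay_per_residue)^k`, the stated per-residue
coverage decay), clamped to the construct bounds and the maximum peptide
length. The remaining reads start and end strictly inside the core.
`decay_per_residue = 0` means extensions are limited only by the bounds
and the length range. Defaults: core 654–709, 70% core prevalence, 200
reads, lengths 8–90, decay 0.2/residue, 10% methionine oxidation.

The bundled parent (`trif_rhim_synthetic()`) is a *synthetic* 112-residue
stand-in for a C-terminal RHIM construct — the genuine sequence is not
redistributed — preserving exactly the features the analysis exercises:
the VQLG tetrad at 663–666, the amyloidogenic nonapeptide PLIIHHAQM
immediately N-terminal (654–662), five methionines, and unique k-mers
(k ≥ 6) so reads map unambiguously.

## Problem sizes and test design

The test suite validates every stage against independent oracles:
brute-force bin-by-bin peak scanning and all-against-all alignment on
100 random fixtures, analytic Poisson laws for backgrounds and false
positives, and ground-truth recovery on simulated mixtures. Recovery
runs use 180 s traces with ≥ 300 green-visible events per trace at dual
fractions 0.1/0.4/0.9 (50 replicates each, recovered RedQ within ±0.05
of the realised ground truth), a 200-replicate independence null at
dual fraction 0, and 20 seeded digests for exact core recovery — sizes
at which binomial error is well inside the stated tolerances while the
full suite runs in well under a minute per criterion.

## Known limitations

* The simulator's species are statistically stationary; aggregation
  kinetics (growing complexes over the record) are not modelled.
* Brightness is a free parameter, not calibrated to any instrument;
  absolute PCH axes are only meaningful relative to the simulation's
  own units.
* colourQ is a detection-level statistic: it cannot distinguish a true
  heteromer from two distinct complexes co-occupying the confocal
  volume, beyond what the chance-coincidence diagnostic quantifies.
* Peptides shorter than the uniqueness scale of the parent sequence may
  map ambiguously and are dropped rather than rescued by fractional
  assignment.
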