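---
title: "Longitudinal immune-phenotype analysis of arrayed microtumours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal immune-phenotype analysis of arrayed microtumours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stampr)
```

## The problem

Arrayed skin microtumour models seed hundreds of clonal tumours into
laser-made dermal pores and image them daily with fluorescence microscopy.
Although genetically identical, neighbouring tumours develop different
*tumour immune phenotypes* (TIPs): **inflamed** (T cells infiltrate the
core), **excluded** (T cells accumulate at the rim), and **desert** (few T
cells at all). Phenotypes interconvert over time, and an early conversion to
the inflamed state predicts spontaneous or therapy-induced rejection.
`stampr` implements the complete quantitative pipeline for such experiments —
from multi-channel time-lapse stacks to per-tumour phenotype timelines,
cytotoxicity indices, Markov transition dynamics, trajectory classes and
per-lesion survival — together with a ground-truthed synthetic generator
that stands in for raw imaging data.

## The synthetic cohort generator

### Phenotype dynamics

Each tumour's per-day phenotype sequence is a realization of a first-order
Markov chain over five integer-coded states: 1 desert, 2 excluded, 3
inflamed, 5 resolved (rejected), 0 mouse death. Resolved and death are
absorbing. The default daily transition matrix
(`default_transition_matrix()`) and day-1 distribution
(`default_start_probs()`) encode an immunocompetent host:

```{r}
round(default_transition_matrix(), 3)
default_start_probs()
```

Two constraints fixed these defaults:

* **Calibration.** The first-passage probability into the resolved state by
  day 14 — computed analytically by matrix powers — is 30.6%, matching the
  ~30% spontaneous rejection fraction seen in immunocompetent hosts over the
  first two weeks.
* **Identifiability of the desert rule.** The classifier's desert threshold
  is the 25th percentile of the cohort's first-imaging-day median T-cell
  intensities. A cohort whose day-1 desert fraction exceeds 25% cannot, by
  construction, have all its deserts below that percentile; the default
  day-1 desert probability is therefore 0.15, leaving headroom for sampling
  noise.

### Growth and rejection kinetics

Areas follow logistic growth `a(t) = K a0 / (a0 + (K - a0) exp(-r (t-1)))`
with a lognormal per-tumour rate (median 0.45/day, sdlog 0.25), carrying
capacity `K = 3` mm² and seeded area `a0 = 0.05` mm². Published array data
show growth kinetics only as curves, so the functional form is this
package's choice; logistic growth is the standard parsimonious model for
space-limited lesions. Once the chain enters the resolved state the area
decays exponentially (2.0/day) and the tumour leaves the detectability set
below 0.01 mm² — rejected tumours fade over one to two days rather than
vanishing instantly, which mirrors how disappearance is observed in images
and explains why image-derived resolution always lags chain-level
resolution.

### Emissions and reproducibility

Conditional on the phenotype, per-day T-cell abundance (lognormal) and core
infiltration ratio (clamped Gaussian) are drawn from `default_emission()`.
The magnitudes are *not* calibrated to real MFIs — no per-phenotype intensity
scales are published — they are chosen so the classifier's decision regions
are realizable: desert abundance far below the cohort 25th percentile,
excluded cores well under the 40% ratiometric cut-off, inflamed cores above
60%.

One global stream is split into per-tumour substreams (a vector of
per-tumour seeds drawn up front), so enlarging a cohort never perturbs
existing tumours, and every stage of the package is bit-reproducible from
its seed.

### The archetype generator

`simulate_archetype_cohort()` generates the control-arm trajectory mixture
used for trajectory-class studies: class I tumours gain T-cell abundance but
stay excluded; class II pass through exclusion and inflame late (switch day
11–14); class III inflame early (day 3–5) with high abundance and
infiltration ratio and are then mostly rejected. Class III is the only
class enriched for rejection, reproducing the qualitative structure of
observed trajectory classes.

## Rendering

`render_timelapse()` draws each tumour as a radially symmetric blob
`I(d) = A exp(-log 2 (d/r)^12)` whose *half-maximum contour sits exactly at
the true equivalent radius*, so any thresholding segmenter that cuts near
half maximum recovers the true area; the steep edge (exponent 12) makes the
recovered area insensitive to the exact threshold. The T-cell channel
encodes the phenotype by construction: nothing for deserts, an annulus
(half-width 20% of the equivalent radius, centred on the mask boundary) plus
a faint diffuse in-mask component for excluded tumours, a filled uniform
disc for inflamed tumours, and a residual T-cell cluster for resolved ones.
The calcium channel is a baseline profile plus Poisson-count transient flash
events; Gaussian and scaled-Poisson detector noise are applied last, and a
ground-truth label image is emitted per frame.

The renderer emulates the *statistical* structure the downstream analysis
assumes — radial intensity organisation, per-phenotype intensity scales,
transient calcium events, detector noise. It does **not** emulate
vasculature or skin autofluorescence, tumour shape irregularity, motion or
registration error between days, the optical point-spread function, or 3-D
structure. Passing tests on these renders therefore validate the *rules and
arithmetic* of the pipeline, not its robustness to real-world imaging
artefacts.

Two default scales are provided. The tabular defaults (`scenario_config()`)
describe mm-scale lesions over 21 days. `imaging_scenario()` provides the
render-scale conditions: an 8×8 array of sub-millimetre microtumours
(`K = 0.8` mm²) at 1.3 mm pitch, 10 µm pixels, 15 daily frames. The pixel
size matters: a tumour at the 0.01 mm² detectability floor spans ~100 pixels
at 10 µm/px, keeping contour pixelization well below the 10% area-accuracy
target, whereas at 25 µm/px the same tumour is a 16-pixel blob whose area is
undefined to within ±20%.

## Segmentation, tracking, response

The published pipeline used a U-net for initial masks followed by manual
editing and manual tracking. The network and the manual steps are not the
analytical contribution, so `segment_frame()` substitutes a classical,
deterministic stage — Gaussian smoothing, Otsu (or fixed) threshold, hole
filling, connected components, small-object removal — and is a pluggable
interface behind which a learned model can be dropped. `link_tracks()`
automates tracking with greedy mutual-nearest-centroid linking under a
displacement cap; unmatched tracks are carried as "not detected" and may
re-match later, unmatched objects open new tracks.

Response classes follow the shrinkage rules: complete responder (CR) when
the tumour is no longer detectable — operationalised as at least two
consecutive trailing undetected frames, so a single dropout is not a CR —
partial responder (PR) when the final area shrank ≥ 20% from the maximum,
and otherwise stable vs progressing disease, split at ±20% of the initial
area (published work reports the merged SD/PD class; `classify_response()`
returns the split labels and offers `merge_sd_pd = TRUE`).

Geometry conventions: (row, col) 0-offset pixel centres; area =
pixel count × (pixel size/1000)²; Feret diameter = maximum pairwise distance
between boundary-pixel centres (hence exactly 0 for a single pixel).

## Spatial statistics

All four statistics operate on the tumour *isosurface* (the segmented mask):

* **Radial profile** — each in-mask pixel gets a normalized radius,
  distance-to-centroid over the equivalent radius √(A/π), clipped to [0, 1];
  20 equal-width bins by default; per-bin medians. The radial coordinate is
  not defined in published methods; equivalent-radius normalization is the
  package's reading (a boundary-distance alternative would differ for
  irregular masks).
* **Abundance index** — per-day in-mask mean (MFI), median across days.
* **Infiltration index** — centre ("central 50% of the isosurface", read as
  50% of mask *area*, i.e. normalized radius ≤ √0.5) over periphery
  (out-of-mask pixels within 50 µm of the border, excluding any other
  tumour's mask — dense arrays make this exclusion necessary); per-day MFIs,
  across-day medians, then the ratio.
* **Infiltration ratio** — median intensity in the core over the maximum of
  the radial profile. The "inner 25%" is read as the inner 25% of the
  normalized *radius* (r ≤ 0.25). Both the area-fraction and
  radius-fraction readings are defensible; each is independently
  configurable (`core_fraction`).

Means are used within a region per day; medians are taken across days, and
across pixels only where a median is explicitly the quantity (profiles,
core). Scale behaviour is tested: abundance scales linearly with intensity,
both ratios are scale-free.

## The TIP classifier

`ratiometric_call()` applies the 60/40 rules: inflamed when the profile over
the inner 25% of the radius is consistently greater than 60% of that
tumour's profile maximum; excluded when consistently less than 40%.
"Consistently" is read in the strictest literal sense — *every* non-empty
inner bin must satisfy the cut-off — with a laxer 80%-of-bins variant
exposed. A profile with a non-positive maximum is indeterminate.

`classify_day()` encodes the precedence, following sentence order of the
source rules: (i) ratiometric inflamed; (ii) ratiometric excluded but core
intensity above the day's inflamed core reference → reclassified inflamed;
(iii) ratiometric excluded; (iv) indeterminate and median intensity below
the cohort desert threshold → desert (the desert rule explicitly requires a
non-excluded profile, which fixes desert-vs-excluded precedence); (v)
otherwise the previous day's phenotype is propagated. Every emitted code
carries a provenance tag, and tag counts reconcile with classified
tumour-days.

Three choices were genuinely open and are package decisions: the desert
threshold uses the linear-interpolation percentile (`quantile` type 7,
conventions differ at small n); the inflamed core reference is recomputed
*daily* from that day's ratiometric inflamed calls in a two-pass sweep
(nothing states whether it is per-day or experiment-wide); and a first-day
indeterminate, non-desert tumour defaults to excluded, the modal early
state. On the first imaging day there is no previous phenotype to
propagate, so some default is unavoidable.

`encode_timeline()` pads timelines after events: 5 from resolution onward, 0
from death onward; when both occur, death overrides resolution only if it
comes first or the same day.

## Influx indices

Four indices quantify cytotoxic attack from minute-scale movies, all
implemented exactly as their defining formulas and checked against naive
loop oracles to 1e-10:

* **Epifluorescence**: per channel, S(t) = in-mask intensity sum; the mean
  absolute consecutive delta of S, normalized by the channel's across-frame
  mean MFI; index = normalized calcium value over normalized reporter value.
  "Averaged … and normalized" is order-independent as written; the package
  normalizes the averaged delta.
* **Two-photon**: the epifluorescence-style ratio (value1) times the ratio
  of mean per-pixel temporal SDs (value2).
* **Confocal calcium / PI**: per-frame median of per-cell MFIs M(t); index =
  mean |ΔM| / mean M. The PI index is structurally identical on the PI
  channel.

All indices are non-negative and invariant to a common positive rescaling.
Masks are held fixed across a movie (matching acquisition-time
semi-automatic segmentation); no photobleaching correction is applied. One
property worth knowing: the delta-sum indices quantify *transient* events.
They grow with the flash rate in the sparse regime (tested up to ~1.5
events/frame) but saturate under near-continuous flashing, because the MFI
normalizer grows roughly linearly with rate while the frame-to-frame delta
grows only like its square root.

## Markov analysis and trajectory classes

`transition_counts()` counts day-to-day transitions per tumour and stops
after the first entry into an absorbing state: timelines are padded with
5s/0s for bookkeeping, and counting those self-loops would let padding
dominate the probabilities (a flag restores the padding-inclusive count).
Rows are normalized to probabilities; empty transient rows are undefined and
absorbing rows get the conventional self-loop 1. `fold_difference()` forms
element-wise treated/control ratios with zero-control cells reported
missing.

`shuffle_null()` randomizes each tumour's pre-absorbing sequence
independently (preserving its state multiset) — the within-tumour reading of
"states were randomized"; a cross-cohort shuffle is a trivial variant left
to the caller. Ten permutations is the reference default; empirical
two-sided p-values use (1 + #extreme)/(1 + n_perm), so p is never zero at
finite n.

`order_timelines()` orders heat-map rows by average-linkage clustering on
Hamming distance. `cluster_trajectories()` clusters the concatenated,
column-standardized per-day (abundance, ratio) series with Ward linkage on
Euclidean distance — the published analysis names neither metric nor
linkage, these are the conventional defaults for trajectory panels — and
chooses k by mean silhouette over 2..6, with a minimum-separation guard
(silhouette < 0.25 reports one effective class) so a duplicated single
archetype is not split. Interior missing days are linearly interpolated,
edges held. Labels are canonicalized by ascending mean infiltration ratio,
making the assignment invariant to input order and aligning label 3 with
the early-inflamed class under the default mixture.

## Survival

Survival units are individual tumours (per-lesion analysis, matching how
array outcomes are reported); intra-mouse correlation is ignored, as in the
source analyses — p-values are anti-conservative to that extent.
`build_records()` takes the event (rejection) time as the first day of code
5, censors at the last observed pre-death day on mouse death, and at the
horizon otherwise. `km_estimate()` wraps the product-limit estimator with
Greenwood variance and log-log 95% bands; `logrank_test()` performs pairwise
log-rank tests against a reference group. `phenotype_at_day()` supports
landmark grouping (e.g. phenotype at day 8, later changes ignored) — the
landmark day is configurable since the grouping convention is not fully
specified in published figures.

## Problem sizes and what the tests show

The packaged checks run, as the package's own choices: generator calibration
at 500 tumours × 21 days; Markov parameter recovery at ≥ 2000 observed
transitions per transient row (max absolute probability error < 0.05,
comfortably within binomial sampling error); trajectory-class recovery on
120 archetype tumours; segmentation/tracking on the 64-tumour
`imaging_scenario()` render (≥ 95% of tumours recovered with median area
error < 10% against ground-truth labels); log-rank type-I error over 500
null replicates of 200 tumours per arm; and exact (1e-10) agreement of every
core statistic with naive brute-force oracles on small fixtures. All
stochastic stages are bit-reproducible under fixed seeds.

These are checks of internal correctness and of recoverability under the
generator's assumptions. They do not certify performance on real
stereoscope data — irregular masks, registration error, autofluorescence and
learned-segmentation behaviour are all outside the synthetic model.
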