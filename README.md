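# stampr

Longitudinal immune-phenotype analysis of arrayed skin microtumours.

Arrayed microtumour experiments seed hundreds of clonal tumours into dermal
micropores and image them daily in multiple fluorescence channels (tumour
reporter, T cells, optionally a calcium sensor). Although genetically
identical, neighbouring tumours develop different **tumour immune
phenotypes** (TIPs) — *inflamed* (T cells in the core), *excluded* (T cells
at the rim), *desert* (few T cells) — that interconvert over time, and early
inflammation predicts rejection. `stampr` is for researchers analysing such
arrays (or benchmarking methods for them): it turns time-lapse stacks into
per-tumour phenotype timelines, cytotoxicity indices, transition dynamics,
trajectory classes and per-lesion survival, and ships a ground-truthed
synthetic generator so every stage is testable without raw imaging data.

## What it computes

* **Synthetic cohorts and renders** — phenotype sequences from a calibrated
  Markov chain over {desert 1, excluded 2, inflamed 3, resolved 5, death 0},
  logistic growth with post-rejection decay, phenotype-conditional
  emissions; multi-channel image stacks with ground-truth labels
  (`simulate_cohort`, `simulate_archetype_cohort`, `render_timelapse`).
* **Segmentation, tracking, response** — smoothing + Otsu + components;
  mutual-nearest-centroid linking; CR/PR/SD/PD calls (CR = no longer
  detectable; PR = ≥ 20% shrinkage from maximum).
* **Spatial statistics** — median radial profile over the normalized radius
  r = d / √(A/π); abundance index (median across days of in-mask MFI);
  infiltration index (centre MFI / ≤ 50 µm periphery MFI, across-day
  medians); infiltration ratio (core median / profile maximum).
* **TIP classification** — the ratiometric rule set: inflamed if the inner
  25% of the profile is consistently > 60% of the tumour's maximum, excluded
  if consistently < 40%; desert if the tumour's median T-cell intensity
  falls below the 25th percentile of first-day medians and the profile is
  not excluded; excluded-with-hot-core reclassified as inflamed; otherwise
  the previous day's phenotype propagates (`classify_tip`).
* **Influx indices** — epifluorescence (normalized mean |ΔS| ratio,
  GCaMP/reporter), two-photon (× pixel-SD ratio), confocal calcium and PI
  (mean |Δ median MFI| / mean MFI).
* **Dynamics** — transition counts/probabilities with absorbing-entry stop,
  treatment-vs-control fold differences, a 10-permutation shuffle null,
  heat-map ordering, and Ward/silhouette trajectory clustering.
* **Survival** — per-tumour Kaplan–Meier with Greenwood log-log bands and
  pairwise log-rank tests, with landmark-day phenotype grouping.

## Worked example

Simulate a 16-tumour array, render it, and run the full image-side pipeline:

```r
library(stampr)

sc <- imaging_scenario(n_timepoints = 10)
cohort <- simulate_cohort(sc$config, n_tumours = 16, seed = 42)
series <- render_timelapse(cohort, sc$layout, imaging = sc$imaging, seed = 43)

labels <- lapply(seq_along(series$days), function(t) segment_frame(series, t))
tracks <- link_tracks(labels, days = series$days,
                      pixel_size_um = series$pixel_size_um)
timelines <- classify_tip(series, tracks)
timelines
#> stamp_timelines: 16 tumours x 10 days
#>   desert excluded inflamed resolved    death
#>       20       77       24       39        0
```

Of the 160 tumour-days, 39 are "resolved": several tumours were rejected and
disappeared from the images. Transition probabilities (rows = from-state):

```r
round(transition_probabilities(transition_counts(timelines))$probs, 2)
#>          desert excluded inflamed resolved death
#> desert     0.71     0.18     0.00     0.12     0
#> excluded   0.08     0.83     0.05     0.04     0
#> inflamed   0.00     0.05     0.81     0.14     0
#> resolved   0.00     0.00     0.00     1.00     0
#> death      0.00     0.00     0.00     0.00     1
```

Inflamed tumours resolve at ~3× the rate of excluded ones (0.14 vs 0.04 per
day in this small cohort). Per-tumour survival:

```r
records <- build_records(timelines, group = phenotype_at_day(timelines, 8))
tail(km_estimate(records), 3)
#>   time n_risk n_event   surv     lower     upper
#> 3    7     12       1 0.6875 0.4046033 0.8562792
#> 4    9     11       3 0.5000 0.2452439 0.7104638
#> 5   10      8       0 0.5000 0.2452439 0.7104638
```

Half the tumours are rejected within ten days. Because this cohort is
synthetic, the calls can be scored against ground truth:

```r
mean(timelines$codes == cohort$codes[, 1:10])        # 0.8125
tip_days <- cohort$codes[, 1:10] %in% 1:3
mean(timelines$codes[tip_days] == cohort$codes[, 1:10][tip_days])  # 1
```

100% of desert/excluded/inflamed days are recovered; overall agreement is
81% only because the image side detects a rejection once the tumour has
decayed out of the images, a day or two after the ground-truth chain enters
the resolved state.

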