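---
title: "Classifying and validating single-particle bioaerosol data from a five-channel UV-LIF sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and validating single-particle bioaerosol data from a five-channel UV-LIF sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wibstools)
```

## The measurement problem

A WIBS-4+ records, for every particle it draws through its optics, an
optical-equivalent diameter (up to 30–40 µm), a dimensionless asymmetry
factor (AF, low for near-spherical particles), and the spectrally
unresolved fluorescence intensity in five excitation/emission channels:
FL1 (280 → 310–400 nm), FL2 (280 → 420–650 nm), FL3 (370 → 420–650 nm),
and two chlorophyll-band channels FL4 (280 → 600–750 nm) and FL5
(370 → 600–750 nm). The aerobiological question is whether selections of
these single-particle events can stand in for the daily pollen-grain and
fungal-spore concentrations that a collocated Hirst-type volumetric trap
(10 L/min, tape counted under a microscope) produces.

`wibstools` implements that analysis as a pipeline of small, testable
stages, and ships a synthetic-campaign generator with known ground truth
so that every stage can be validated end to end even though no field
campaign data are released with it.

## Threshold calibration

Fluorescence baselines come from forced-trigger mode: the instrument
fires on particle-free air, and each channel's background intensities
are summarised by their mean and sample (n−1) standard deviation. The
channel threshold is `mean + k·sd` with `k ∈ {3, 6, 9}`; a particle is
fluorescent in a channel when its intensity *strictly* exceeds the
threshold. Strictness is a convention we fix here (the boundary case is
not observable in continuous data but matters for reproducibility); so
is the sample standard deviation, chosen over the population form because
a daily forced-trigger session is a finite sample of the background
process.

`k = 3` is the conventional baseline. Escalating to 6 or 9 raises every
threshold by whole background standard deviations and is the standard
defence against weakly fluorescent anthropogenic interferents (PAHs,
HULIS, soot), which sit just above the 3σ level, while strongly
fluorescent biological particles are essentially unaffected. Because
thresholds are monotone in `k`, the fluorescent sets at 9σ ⊆ 6σ ⊆ 3σ —
a property the test-suite checks on every generated campaign.

Daily sessions can be combined by `aggregate_daily_thresholds()` under a
`mean` (default) or `latest` policy; the per-channel relative spread
across sessions is always reported as the stability check. The pipeline
applies one threshold set to a whole campaign unless per-day sets are
requested explicitly.

## Classification

The Perring class is the label spelled by which of FL1–FL3 a particle
exceeds (A = FL1, B = FL2, C = FL3, concatenated: AB, AC, BC, ABC, or
NonFluorescent), and the chlorophyll class by FL4/FL5 the same way
(D, E, DE, None). Both labellings are mutually exclusive and exhaustive
by construction, and the implementation is tested against an
independently coded 32-pattern lookup table.

One genuine ambiguity is what "fluorescent" means for the overall
fluorescent fraction once FL4/FL5 exist: a D-only particle exceeds no
traditional channel. We default to counting exceedance in *any* of the
five channels (`fluorescence_basis = "fl12345"`) because the added
channels are real detectors and a particle seen only by them was still
detected fluorescing; the traditional three-channel basis remains
available as `"fl123"`, and both are computable from the same classified
table. Saturated intensities (at the configurable detector ceiling,
default 2047 units) classify normally and carry a flag.

## Proxy filters

The named selections in `builtin_proxies()` encode the size/class/
intensity rules used for taxon-level comparison: a 2 µm floor for every
Hirst comparison (the microscopic method is unreliable below ~2 µm),
A-class at 9σ and A+AB at 3σ for fungal spores, A+AB under 5 µm for
ascospores, A under 10 µm for *Cladosporium*-like spores, FL2 and FL3
above 1300 detector units (raw, at the 3σ classification) for total
pollen, ABC above 25 µm for tree pollen, and chlorophyll-D selections at
10–15 µm (herb) and above 10 µm (grass).

Endpoint conventions are centralised in the filter objects: "greater
than" and "less than" are strict, the 10–15 µm range is closed. The herb
and grass windows overlap deliberately — a 12 µm D-type particle
satisfies both — because the two rules are defined independently; the
package keeps both as stated rather than inventing a partition. Filters
are conjunctive and idempotent, and each records the σ multiplier its
classification must have used; applying a filter to a classification
made at a different multiplier is a configuration error, not a silent
reinterpretation.

## Concentrations and diurnal profiles

A selection becomes a number concentration through the sampled volume:
`count / (flow × bin duration)`, reported per m³. The WIBS sample flow
is not a published constant of the instrument; the default here is
0.23 L/min and every concentration series records the flow it used.
Days are calendar days in local campaign time (timestamps are never
timezone-converted), matching the daily segments a Hirst tape is cut
into. Bins without instrument uptime are *missing*, not zero; a day is
reported when at least 75% of it was covered (configurable), which
reproduces the usual practice of dropping power-loss days.

Diurnal profiles average concentration by hour of day across days and
normalise by the maximum hourly mean (peak = 1); mean-normalisation is
available by flag. Max-normalisation is the default because the shape of
interest — where the early-morning fungal peak sits — reads directly off
the peak position.

## Comparison statistics

Daily WIBS and Hirst series are inner-joined on date (missing days drop
out; n is always reported). `correlate_series()` reports Pearson r,
linear R² (= r², asserted to 1e-10 in tests) and a polynomial R²
(degree 2 by default — the minimal curvature extension; higher degrees
invite overfitting 50-point series), on raw untransformed
concentrations. An optional flag drops a stated number of
largest-residual points for outlier-sensitivity checks; it is off by
default. High-day co-occurrence uses strict exceedance of
50 / 80 / 80 / 2500 per-m³ thresholds for grass / herb / tree / fungal
and reports exact Euler-region counts over the 15 non-empty group
combinations.

`sigma_escalation()` ties the calibration, classification and comparison
stages together: recompute thresholds at each `k`, re-classify,
re-filter, re-aggregate, re-correlate. On the synthetic scenario this
reproduces the qualitative escalation effect: interferents placed
between the 3σ and 9σ thresholds pollute the A/AB classes at 3σ and
vanish at 9σ, and much of the AB class shifts to A as FL2 drops below
its raised threshold.

## Clustering

K-means runs on z-score-standardised FL1–FL5, size and AF (constant
features are dropped with a warning). Standardisation is the natural
reading of "scaled": the seven features differ by orders of magnitude in
units, and any unscaled distance would be dominated by the bright
channels. Each fit takes a mandatory seed and keeps the best of 10
random restarts by within-cluster sum of squares; the per-restart
objectives are retained so the "restarts return the minimum" property is
testable. The cluster count is selected over k = 2..12 by the
Calinski–Harabasz index `(B/(k−1))/(W/(n−k))`, implemented in-package
and verified against a brute-force dispersion computation.

`intra_category_cluster()` applies a proxy filter before clustering —
refining the fungal-like A+AB selection, or the high-FL2/FL3 pollen-like
selection, into sub-populations. `map_clusters_to_taxa()` then builds a
daily series per cluster and greedily grows, per taxon, the union of
clusters (capped at 2 by default) maximising linear R²; the greedy union
never does worse than the best single cluster, and taxa with zero
variance over the paired days are flagged and excluded rather than
producing undefined correlations.

## The synthetic campaign generator

Because no field data accompany the method, the generator is a
first-class module whose defaults *are* the study conditions:

* **Structure.** 50 days from 2017-04-21; WIBS flow 0.23 L/min; a
  5000-firing forced-trigger session with background mean 50 and sd 10
  in every channel (3σ threshold ≈ 80, 9σ ≈ 140 detector units).
* **Classes.** Seven populations: ascospore-like (FL1 ≈ 600, FL2 just
  above the 3σ threshold so the class reads AB at 3σ and shifts to A at
  9σ; ~3 µm; dominant 04:00–06:00 emission peak with a weaker evening
  rise), *Cladosporium*-like (FL1-only, ~6 µm, same diurnal shape),
  tree pollen (bright in all of FL1–FL5, hence ABC + DE; ~30 µm;
  midday), grass pollen (D-type chlorophyll signature with high FL2/FL3,
  ~32 µm, capture efficiency 0.35 to model the undersampling of large
  grains at the low WIBS flow), herb pollen (D-type, 10–15 µm), a
  weakly fluorescent anthropogenic interferent placed *between* the 3σ
  and 9σ thresholds in FL1/FL2, and non-fluorescent dust. Intensity
  levels are truncated normals in detector units; sizes are lognormal;
  all values are clipped to the instrument bounds.
* **Counting model.** Per class and day, a mean-preserving lognormal
  day effect with a class CV (0.9–1.1 for biological classes) scales the
  mean concentration; thinning by capture efficiency and conversion
  through the sampled volume gives a Poisson-realised count; timestamps
  follow the hourly emission weights.
* **Hirst observation.** The paired daily series applies multiplicative
  mean-preserving lognormal counting noise with CV 0.30 — the upper
  bound of the slide-transect extrapolation error — per class and day,
  then aggregates to taxon and group labels. Interferents and dust are
  not counted by microscopy and never appear in the Hirst table.
* **Blindness.** The particle table contains only what the instrument
  records; true class labels travel in a separate aligned vector.

What the generator does *not* emulate: meteorological modulation of
emission and sampling efficiency, wind-direction-dependent Hirst
overestimation (available as an optional per-day factor but off by
default), spore release in clusters misread as single large particles
(an optional switch was considered and left out of the default
conditions), atmospheric ageing of fluorophores, and any correlation
between classes' day effects. Passing tests therefore demonstrate that
the pipeline recovers a truth *of this structure* — independent
lognormal day effects observed through Poisson counting and lognormal
counting error — not that the instrument itself performs this way in
the field.

## Problem sizes and numerical choices

The default scenario produces roughly 120,000 particles over 50 days,
which the test-suite uses in full for the recovery checks; the
unit-level property tests run on campaigns of 2–12 days. Cluster-number
selection in the analysis scripts searches k = 2..12 with 10 restarts;
the acceptance checks use smaller ranges where the fixture has a known
class count. Ties in k-means restarts resolve to the first minimum;
`findInterval` bins timestamps left-closed; concentrations in bins with
zero counts are exactly 0 while unpowered bins are `NA`. Degenerate
inputs fail loudly: fewer than two forced-trigger records, correlation
on constant series, empty pre-selections and σ mismatches are all
errors, never silent recoveries.

## Known limitations

* The grass proxy inherits both the herb-window overlap and the strong
  undersampling of large grains, so its daily agreement is structurally
  the weakest of the pollen groups — on synthetic campaigns as in
  practice.
* The Calinski–Harabasz criterion favours compact spherical clusters in
  the standardised space; populations that differ mainly in one bright
  channel can merge at the selected k. The per-k index vector is always
  returned so that plateaus can be inspected.
* Concentrations assume a constant flow over a bin and make no
  inlet-loss or sampling-efficiency correction; capture efficiency
  exists only inside the generator as a truth-side effect.
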