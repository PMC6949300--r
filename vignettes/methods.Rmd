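---
title: "Methods: land-use typology and aboveground carbon accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land-use typology and aboveground carbon accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landcarbon)
```

## The problem

Intensively managed subtropical forest landscapes — rotation forestry,
fast plantations, passive recovery of abandoned farmland — change too
quickly for a single land-cover map to describe them. `landcarbon`
implements a pipeline that reads an *annual forest-probability* series
per 500 m × 500 m pixel (16 years, 2002–2017 by default), decomposes
each pixel's trajectory into piecewise-linear segments, classifies the
pixel into one of eight land-use types, and accounts for the
aboveground carbon consequences per type: annual stocks, gross gains
and losses, net sinks, contributions to the regional sink and fractions
of fossil emissions offset. A companion stage filters L-band microwave
vegetation optical depth (VOD) and soil-moisture (SM) series at 25 km
resolution and tests per-cell trends, because L-band VOD senses total
aboveground biomass without canopy saturation and SM responds to the
water cost of plantations.

Every stage is exercisable end to end on synthetic scenes with known
ground truth; nothing in the package downloads or requires satellite
data.

## Forest probability and preprocessing

The forest-probability input is the vote fraction of a probabilistic
binary classifier: 0 means confidently non-forest, 1 confidently
forest, and intermediate values track the within-pixel forested
fraction. `train_forest_classifier()` fits a bagged-tree ensemble on
labelled points (7 reflectance bands + elevation) and reports a 3-fold
cross-validated correlation; `predict_probability()` maps annual band
stacks to annual probability maps. Daily images are reduced by
`annual_median_composite()` (per-pixel median of valid observations)
and the annual series denoised by `moving_median3()`.

Two numerical choices worth stating:

* **Median window alignment.** A 3-year moving median of a 2000–2017
  series must drop two years. A *trailing* window (year *t* = median of
  *t−2..t*) yields exactly the 2002–2017 span the analysis uses, so
  trailing is the default; a centered alignment is available by
  argument.
* **Classifier family.** The contract is only "probabilistic ensemble
  output in [0, 1]". No tree-ensemble package is assumed; the package
  carries a compact CART engine (`bagged_trees()`, `boosted_trees()`)
  so installation needs nothing beyond base R and a few utility
  packages.

## Temporal segmentation

`segment_series()` fits a continuous piecewise-linear trajectory with
at most six segments whose vertices sit on observation years, the
segmentation style popularised by LandTrendr for disturbance mapping.
Two properties matter for everything downstream:

1. **Exactness.** For a fixed segment count *k* the model is linear in
   its parameters once the vertex years are fixed (basis
   {1, *t*, hinge(*t* − *v*)}), so the best placement is found by exact
   least squares over all C(n−2, k−1) interior-vertex placements — at
   most 2002 for a 16-year series. A shared orthonormal basis is
   precomputed per year-grid, which makes scoring a placement one
   matrix–vector product; scenes with many identical (noise-free)
   trajectories are additionally memoised. A brute-force oracle
   (independent `lm()` fits per placement) pins this core in the test
   suite.
2. **Parsimony.** The segment count is the smallest *k* whose fit is
   *not significantly worse* than the richest allowed fit, by a partial
   F-test at α = 0.05. A strictly sequential test (*k* vs *k*+1 only)
   was tried first and rejected: for a noise-free rotation sawtooth no
   single added vertex improves the 1-segment fit significantly, so
   sequential selection stalls and harvest cycles are never seen. The
   fit-then-simplify direction matches how LandTrendr itself prunes
   vertices. Ties between equal-SSE placements break toward the
   earliest vertices, for determinism.

Interior gaps of at most two consecutive missing years are linearly
interpolated; longer gaps mask the pixel rather than inventing data.

## Disturbance indices and the eight types

Each segment's velocity is its |magnitude| / duration. The *managed
forest increase* (decrease) index is the largest velocity over positive
(negative) segments — near 1 for a full transition within a year
(plantation or clear-cut), near 0 for slow change. Indices are binned
[0, 0.2) very low, [0.2, 0.4) low, [0.4, 0.6) intermediate, ≥ 0.6 high;
a segment with velocity ≥ 0.4 counts as a *major disturbance*. Bin
edges are left-closed because the printed intervals ("0–0.2",
"0.2–0.4") do not state boundary semantics.

`dynamics_class()` assigns nine trajectory classes from threshold
crossings (0.8 dense, 0.5 forest) and disturbance presence, and
`landuse_type()` maps (increase index, decrease index, dynamics class)
to the eight final types with a priority-ordered, total rule table. The
authoritative combination table was never published; the reconstruction
here satisfies every stated constraint (persistent types require both
indices < 0.4; afforestation requires a rapid gain and no major loss;
rotation_L requires a downward transition with regrowth and a decrease
index > 0.6) and sends every residual disturbed combination to
*rotation*, the generic managed-change type. The table is deterministic
and replaceable via `typology_config()`. A useful symmetry holds by
construction and is property-tested: reversing a series in time swaps
the upward and downward transition classes (4↔6, 5↔7) and swaps the two
indices.

## Carbon accounting

`train_cdensity_model()` calibrates boosted regression trees against a
single-date benchmark density map (50/50 train/validation split,
reporting held-out *r*, slope and RMSE), and the model applied per year
gives annual density maps. `carbon_account()` then computes, per type
and for the region: annual stocks (density × 25 ha × 10⁻⁹ → Pg C),
gross gains/losses as sums of positive/negative year-to-year stock
deltas, the net sink, contributions and emission offsets
(CO₂ ÷ 3.67 → C; offsets averaged over 2002–2015 by default).

* **Net sink definition.** The endpoint difference over (n−1) years is
  the default, because the gross gain/loss decomposition satisfies
  gain − loss = end − start exactly, making the accounting identities
  testable to 10⁻⁹; an OLS-slope alternative is one argument away.
  Both agree exactly on linear stock trajectories.
* **Rounding.** Report tables print integer percentages except values
  below 1 % in magnitude, which keep one significant digit (0.78 → 0.8,
  −0.061 → −0.06); this reproduces the mixed precision of the reference
  accounting table the worked-example tests check against. Notably,
  that table's per-type contribution column is
  arithmetically consistent only with the large-scale-rotation sink
  value printed in the running text (0.0009 Pg C yr⁻¹), not with the
  table's 0.0008 — the worked-example tests use 0.0009.
* **Timber.** Harvested volume × wood basic density × 0.5 → carbon.
  The basic density default is 0.45 Mg m⁻³, a mid-range average for
  pine, cedar and eucalyptus, the common plantation species of
  subtropical China; it is configurable and only scales the timber
  series.

## Microwave filtering and trends

`quality_filter()` drops observations with any scene flag, soil
temperature < 273.5 K or TB-RMSE > 10 K (an RFI proxy).
`smooth_and_deoutlier_vod()` applies a centered 30-day calendar-window
moving average per orbit, excludes observations whose residue (raw −
smoothed) falls strictly below the 10th or above the 90th percentile,
and re-smooths the survivors; the exclusion is applied once, not
iterated, and a degenerate all-equal-residue series loses nothing
(deleting 20 % of a perfect series would be absurd).
`combine_orbits()` merges ascending and descending series keeping the
30 lowest-TB-RMSE observations per year, ties broken by date.
`vod_to_cdensity()` fits a four-parameter logistic between
reference-period mean VOD and benchmark density per cell (monotone
saturating, as biomass–VOD relations are), averaging the series from
two benchmarks when two are given.

`cell_trends()` fits per-cell OLS slopes on annual means with a
two-sided t-test; since only "significant (p < 0.05)" is pinned down,
a rank-based Mann–Kendall + Sen-slope alternative sits behind an
argument. Under a null
grid the one-sided significant-decline rate is α/2 = 2.5 %, and the
test suite verifies the empirical size sits in [1.5 %, 3.5 %] over
2000 cells. When 8 % of cells carry a strong planted decline, the
detected fraction is expected at 0.08 + 0.92·0.025 ≈ 10.3 % — planted
declines plus false positives — and the acceptance test checks that
expectation within binomial error plus ≥ 95 % power on the planted
cells; a test demanding exactly 8 % would be wrong about its own false
positives.

## The synthetic world

`generate_scene()` draws each pixel from one of eight trajectory
archetypes with additive Gaussian noise clipped to [0, 1] (the simplest
noise consistent with a probability-valued signal). Template levels are
0.2 (non-forest), 0.65 (forest), 0.9 (dense forest); recovery rises
over 10 years, deforestation declines over 4, rotation grows for a
5-year cycle and is clear-cut to the non-forest level in a single year,
and rotation_L holds dense cover, suffers a deep 1-year harvest and
regrows rapidly but stays below the forest threshold. One deliberate
deviation: afforestation's change duration is **1 year**, not 3 — a
3-year change can never reach a managed-forest index of 0.4 (its
velocity is at most 1/3), so a 3-year template could never be labelled
afforestation by the very rules it is meant to exercise.

The default benchmark law is linear, 118·p − 1.6 Mg C ha⁻¹ floored at
zero, so dense-forest, forest and non-forest pixels average ≈ 105, 75
and 22 Mg C ha⁻¹ — the reference per-type density regime. Coarse-grid
series carry imposed linear trends, mild seasonality, gamma-distributed
TB-RMSE and Bernoulli flags. Province tables anchor the regional
emission series at 0.21 Pg C (1997) rising to a 0.63 Pg C plateau
(2012), and the timber ramp at 0.004 → 0.012 Pg C (2003 → 2017);
seeds perturb only province shares, never the regional anchors.

What a green test does **not** establish: the generator has no spatial
autocorrelation, no mixed pixels, no cloud artefacts, no
radiative-transfer physics and no within-type spread of cycle lengths
or onsets beyond what parameters request. Recovery of ground truth here
shows the algorithms are correct, not that real-world accuracy matches.

## Known limitations

* Raster I/O is plain text (CSV + JSON sidecars); GeoTIFF/NetCDF
  bindings were deliberately left out to keep the dependency footprint
  at base R + jsonlite/yaml/digest.
* The land-use rule table is a reconstruction (see above), flagged and
  config-replaceable.
* The segmentation does not implement angle-based vertex simplification
  or recovery-rate filters; nothing indicates they were used for this
  style of application, and the F-test pruning covers parsimony.
* Areal normalisations that require the real region's area (e.g. sink
  per hectare of the full study region) are out of scope.
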