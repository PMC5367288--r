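---
title: "Methods: vertical habitat use, dive typing and mortality screening from PSAT records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vertical habitat use, dive typing and mortality screening from PSAT records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`reefdive` analyses pop-up satellite archival tag (PSAT) time–depth records
from reef-associated sharks: where in the water column an individual lives,
how its off-bank excursions are structured, what temporal covariates shape
its vertical habitat use, and whether the record is contaminated by
post-release mortality. This vignette is the package's own account of the
methods, their assumptions, and the design choices that were genuinely open.

## Data model

A tag record is `(timestamp UTC, depth m, temperature °C, delta-limited
flag)`; depth is positive down with a −1 m surface-noise tolerance (clipped
to 0 for analysis, preserved raw) and a 2100 m ceiling (the deepest basin in
the study system). Deployment metadata carry the tagging location, animal
covariates (sex, stretched total length), deployment window, and the tag's
programming: high-rate tags sample ~5 min with no geolocation; standard-rate
tags archive at 2 min but transmit a 15–60 min subset through Argos.
Delta-limited records (transmitted changes that clipped the encoding range)
are retained in every analysis — they are valid, if truncated, observations.

Temporal gaps are intervals between consecutive records longer than 1.5× the
nominal resolution. The multiplier is a package decision (no published
quantification exists): it tolerates transmission timing jitter up to half a
sampling interval while catching any fully dropped record. It is the
`gap_factor` argument everywhere it matters.

## Diel, lunar and seasonal context

Sunrise and sunset come from the NOAA solar-position equations at zenith
90.833°; the test suite holds them to within 3 minutes of an independent
ephemeris oracle (solar altitude root-finding with the Astronomical Almanac
low-precision series, computed separately and frozen). Dawn and dusk are the
2 h windows centred on sunrise and sunset, half-open on the right so that
DAWN/DAY/DUSK/NIGHT exactly partition every day — the partition property is
tested by counting minutes. Lunar illuminated fraction uses the low-precision
Meeus elongation series (tested against published USNO new/full moon dates)
and is binned into five 20% levels; computing rather than fetching it keeps
the package network-free. Seasons are meteorological Northern-Hemisphere
months (Dec–Feb winter, and so on): the analysis needs an unambiguous
four-level factor and nothing in the data constrains a different boundary.
Moon phase is only identifiable over at least two synodic months, so
deployments shorter than 59 days exclude the moon term from the models.

Solar events use the fixed tagging location; an optional per-day location
table can override this for standard-rate tags with daily geolocations
(geolocation filtering itself is out of scope). Lunar binning uses the daily
illuminated-fraction value, not phase-cycle position — the two differ only
in how waxing and waning days interleave within a bin.

## High-use depth bands

The depth distribution is estimated with R's `density()` defaults — Gaussian
kernel, Silverman's `nrd0` bandwidth, 512 grid points spanning the data
range ± 3 bandwidths — because that is what practitioners apply to
time-series depth records, and the band definition (density > 0.01 per
metre) is calibrated to those defaults. Maximal grid runs above the
threshold become bands, clipped below at 0 m and reported at grid
resolution; sub-grid interpolation would pretend to more precision than a
kernel estimate has. Occupancy is the percentage of records inside
`[lower, upper]`. Lowering the threshold can only widen bands (tested as a
monotonicity property). The acceptance suite checks that on the bundled
resident scenario over a 90-day deployment the single detected band
recovers the generator's band centre ± 2 SD within one grid step, and that
a bimodal depth distribution yields exactly two bands. Two caveats are
inherent and worth stating: the threshold edge of a Gaussian band sits at
≈ 2.02 effective SDs (bandwidth widens the kernel estimate slightly), and
with a strongly autocorrelated baseline the realized band centre of a short
deployment wobbles by a few tenths of a metre around its nominal value — so
short (≤ 30-day) tracks cannot pin band edges to grid resolution.

## Off-bank excursions

A dive event is a maximal run of records strictly deeper than 50 m — the
bank edge in the study system is a near-vertical escarpment from 20–30 m, so
50 m is an unambiguous departure; a record exactly at 50.0 m is on-bank
(ties are measure-zero at sensor resolution). The event is bounded by the
last shallow record before and the first after the run, and duration is
measured boundary to boundary: that convention, not first-to-last
sub-record, is what makes a single-sub-record dive at 2-min resolution last
exactly 4.0 min, matching the printed minimum dive duration. Events
truncated by the deployment edges, or whose boundary-to-boundary profile
overlaps a temporal gap, are kept but flagged `rejected` and excluded from
metrics, rates and clustering — an audit trail instead of silent deletion.
Only series at ≤ 5 min resolution are segmented at all; coarser transmitted
sets cannot resolve dive structure.

Switch count is the number of sign changes in consecutive depth differences
over the boundary-to-boundary profile, ignoring zero differences so that
sensor quantisation plateaus do not masquerade as oscillations. Descent and
ascent rates average Δdepth/Δtime over all increasing and decreasing record
pairs respectively. The test suite pins segmentation to a brute-force
single-pass oracle on 1 000 random gap-seeded series (event-for-event,
boundary-for-boundary, including the rejection set — a partition property),
and switch counts to an independently hand-looped sign-change count on 50
constructed profiles.

Inter-excursion intervals run end-boundary to next start-boundary (median
and IQR in hours, maximum in days); dive rates divide per-type counts by
tracked hours with gap time excluded (configurable to the raw span — the
choice only matters for very gappy transmitted sets).

## Dive classification

The five dive variables are natural-log transformed (rates floored at
0.001 m s⁻¹, just below the smallest plausible measured rate, to keep the
log finite), centred and scaled, then decomposed into principal components
of the correlation matrix; because the variables are pre-scaled, covariance
and correlation PCA coincide. Components with eigenvalue ≥ 1 (latent-root
criterion, cutoff exact) are retained. k-means (Hartigan–Wong, 20 restarts,
fixed seed) runs over k = 1..8 and R²(k) = 1 − WSS/TSS is recorded; the
published selection rule is visual, so the implemented rule — smallest k
whose marginal gain to k+1 falls below `min_gain` — is explicitly a
calibration: `min_gain = 0.1` is set so that the bundled three-type preset
yields k = 3 (under this generator the R² gain from 3 to 4 clusters is
0.06–0.09, so the older conventional 0.05 cutoff over-splits). Both the
cutoff and a `k_override` are exposed.

With k = 3 the semantic labels are: *directed* = highest median maximum
depth (tie broken by descent rate), *extended* = highest median duration of
the rest, *transitory* = remainder; a warning fires if the directed cluster
is not also the fastest, since that combination is what the label means.
The acceptance suite generates 600 dives per seed from the three type
presets and requires, over 10 seeds, k = 3 via the elbow and an adjusted
Rand index ≥ 0.8 against the generator's labels.

## Mixed-effects models

Records are aggregated per individual × local date × diel period into mean
depth and the count of records deeper than 50 m. Both responses are
log(x + 1)-transformed: both are right-skewed, and +1 keeps empty-count
cells finite (the published analysis log-transforms but does not say how it
resolved zero counts; `log(x+1)` on all cells is this package's resolution,
applied to the mean-depth response too so the two models share a scale).
Models are linear mixed models (`lme4::lmer`) with a random intercept per
individual, REML for reported fits. Stretched total length is centred. The
full fixed-effect set is moon bin, season, diel period, sex, site and
length.

Backward elimination drops, at each step, the least-significant fixed
effect with p > 0.05, where whole-factor p-values come from
likelihood-ratio tests on maximum-likelihood refits (REML likelihoods are
not comparable across fixed-effect structures). Full and reduced models are
reported side by side with AICc (= AIC + 2p(p+1)/(n−p−1)) and BIC so the
parsimony comparison is checkable. Pairwise level contrasts use
`multcomp::glht` single-step ("Tukey") family-wise adjustment; unadjusted
p-values are reported alongside, and adjusted ≥ unadjusted is a tested
invariant.

The recovery study (`simulate_period_summaries()`) generates summaries
directly on the log scale with known effects, a known individual SD, and a
balanced, near-orthogonal sex/site assignment. The effect sizes are set by
a power analysis, not by tuning: site and sex are between-individual
effects, so with 10 individuals and individual SD 0.3 a balanced contrast
has SE ≈ 0.3·√(2/5) ≈ 0.19, and retaining the effect in ≥ 90% of cohorts at
α = 0.05 needs an effect ≥ ~3.2 SE ≈ 0.62 — hence 0.7 on the log scale; the
within-individual diel effect (−0.3, DAY shallower) is powered far beyond
that at ~4 800 rows per cohort. The acceptance suite runs 100 such cohorts
(10 individuals × 120 days) and requires the diel/site/sex effects retained
with the correct sign, and the null moon effect eliminated, in ≥ 90% each.

## Mortality / tag-consumption screening

Two signatures, both configurable: a depth plateau — the longest window of
records deeper than 200 m whose depth range stays within 5 m, flagged at
≥ 6 h — and a temperature lag — the cross-correlation between depth
differences and negated temperature differences peaking at a lag ≥ 1 sample
with a ≥ 0.1 correlation advantage over lag 0. The thresholds are package
choices: they separate a mortality trace (~1000 m held for most of a day,
a tag reading a predator's gut) from the longest ordinary extended dives
(well under 7 h, never depth-stable within metres) by a wide margin. The
post-plateau diel oscillation pattern that a predator can produce is
reproduced by the simulator but deliberately not used as a trigger — it is
too predator-specific. Flagged tags are excluded from all downstream stages
(override available). The acceptance suite requires exact recovery of
injected lags 1–10 and zero false flags over 50 resident-scenario seeds.

## The synthetic-data generator

`simulate_track()` emulates the statistical structure the analyses assume:

- **Baseline band**: a bounded AR(1) (φ = 0.98) around the seasonal band
  centre with stationary SD `band_sd`, clipped to [0, 49.5] m — giving the
  serial correlation that real tag series have, so gap logic, KDE bands and
  aggregation face realistic input. Defaults (centre 18 m, SD 5 m) place the
  band where published band tables put it, in the top 50 m.
- **Excursions**: an inhomogeneous Poisson process with per-diel-period
  rates (night-biased defaults), thinned record-by-record; the diel lookup
  uses the same assigner as the analysis, so generator and analyser can
  never disagree about period boundaries. Each event is a piecewise-linear
  profile — descent, optional bottom hold, oscillations, ascent — drawn
  from per-type shape distributions. The three morphologies (transitory:
  short/shallow; extended: long/oscillating — always at least one
  oscillation, that is what the type means; directed: deep/fast) are
  parameterised from published per-cluster median (IQR) values via exact
  lognormal quartile matching, with tails truncated at the published
  per-cluster ranges. Durations are *emergent* from the geometry
  (depth ÷ speed + oscillation time), which is both how real dives work and
  what makes the five variables properly correlated within type; the
  bottom hold guarantees a sub-threshold dwell longer than one sampling
  interval so every generated event is detectable, while single-sub-record
  dives (a quarter of real events) remain common.
- **Temperature**: `sst(season) − 0.03 °C/m × depth` plus noise. The linear
  thermocline is deliberately crude; its slope reproduces the published
  surface-to-436 m temperature span. It is wrong in detail below a few
  hundred metres (real profiles flatten), which matters to nothing
  downstream except cosmetics of the mortality trace.
- **Transmission**: subsampling to the transmitted resolution plus random
  contiguous block dropout, exact to the requested fraction, deterministic
  per seed.
- **Mortality overlay**: steady sink at 0.25 m s⁻¹ to a 1035 m seafloor,
  an 18 h plateau, then diel oscillations between 400 and 650 m; the
  temperature channel is the depth-implied ambient temperature delayed by
  `temp_lag` samples plus noise.

What passing tests on this generator do **not** show about real data: the
generator has no tidal or thermally driven fine-scale depth structure, no
vertical sensor drift, no light channel, no horizontal movement, and its
dive types are cleanly separated by construction — real dive-type mixtures
grade into each other, and a real adjusted Rand index against "truth" is
unknowable. The generator answers *does the machinery recover known
structure*, not *is the biology three-typed*.

## Problem sizes and determinism

The test suite runs: the segmentation oracle on 1 000 random 300-record
series; 50 constructed switch-count profiles; cluster recovery on 10 × 600
dives; band recovery on one 90-day track; model recovery on 100 cohorts of
10 individuals × 120 days; and the mortality screen on 10 injected lags
plus 50 30-day resident seeds. These sizes were chosen as the smallest that
make the stochastic assertions stable. Every simulation, clustering and
pipeline run is deterministic given its seed; the pipeline writes
byte-identical artefacts for identical configurations (tested).

## Known limitations

- Band edges are meaningful only to about the KDE grid/bandwidth scale, and
  on short deployments the realized band of an autocorrelated process
  wobbles around its nominal position; treat printed 0.1 m precision as
  display, not accuracy.
- The deep-count model is a log-linear approximation, not a count GLMM;
  zero-heavy cells at coarse transmitted resolutions would favour a
  Poisson/negative-binomial family (out of scope here).
- The mortality screen is tuned for consumption-style signatures; tag
  shedding with surface floating, or mortality without a predator, produce
  different traces it does not target.
- Whether archived or transmitted record sets should feed the band
  estimator for recovered tags is not resolvable from published sources;
  the package uses all available records.
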