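---
title: "Modelling grapevine cold hardiness from daily weather records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling grapevine cold hardiness from daily weather records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hardivine)
library(dplyr)
```

## The problem

Dormant grapevine buds survive winter only while the air temperature stays
above their current cold hardiness, expressed as LT50 — the temperature
killing half the primary buds. LT50 is dynamic: chill accumulation drives
*acclimation* (hardiness deepens through autumn into midwinter) and warm
spells drive *deacclimation* (hardiness is lost, rapidly so in late winter),
so each dormant season traces a U-shaped LT50 trajectory whose interaction
with cold snaps determines bud survival. `hardivine` models that trajectory
from the two quantities long-term weather archives actually contain — daily
maximum and minimum temperature — and converts the gap between daily minima
and LT50 into a bounded damage score suitable for climatological mapping.

## Curation model

Stations enter the analysis through four ordered filters, each with a tunable
threshold in `curation_config()`:

* **record type** — a station must have days carrying *both* extremes, with a
  first-to-last span of at least `min_station_years` (default 2, counted as
  calendar span ≥ 730.5 days);
* **geographic** — `abs(latitude)` must fall inside `latitude_band`
  (default 30–55°, inclusive at both edges; the band is symmetric so both
  hemispheres' viticultural zones pass);
* **temporal** — records before `temporal_cutoff` (default 1960-01-01) are
  discarded, and stations with nothing after the cutoff drop out;
* **quality** — each dormant season must have at least `min_season_days`
  (default 220) days carrying both extremes.

Dormant seasons run 1 September–1 May in the northern hemisphere and
1 March–1 November in the southern. Windows are closed at the start and open
at the end (30 April / 31 October are the last days), giving 242–243 possible
days in the north; a season is labelled by the calendar year of its start
date, and leap days count toward the total. The band edges and the 220-day
threshold are treated as inclusive keep-conditions; both conventions are
configuration, not hidden constants, and the test suite pins the keep/drop
boundary at exactly `min_season_days`. Because a station that fails an early
filter is never passed to later ones, the curation report records only the
first failure per station, and re-running curation on its own output changes
nothing (idempotence is a tested property).

## Hourly reconstruction

Chilling and heat-accumulation models are defined on hourly temperatures, so
daily extremes are expanded through an idealised diurnal curve: temperature
rises from the day's minimum at sunrise along a sine with a peak equal to the
day's maximum, and decays logarithmically overnight toward the next day's
minimum at the next sunrise. Sunrise and sunset come from standard solar
declination geometry (local solar time, symmetric around noon), so the curve
needs only latitude and day of year. Two guards keep the contract exact: the
hour nearest the sine peak is pinned to the day's maximum, and night hours
are capped at the day's maximum so an incoming warm front cannot push a
night hour past the day's own tmax. Latitudes at or beyond 66.6° are
rejected (polar day/night breaks the geometry). Daily gaps up to
`gap_max = 3` consecutive days are linearly interpolated before
reconstruction; longer gaps abort feature extraction for that season even if
it passed the 220-day rule — interpolating a week of winter weather would
manufacture exactly the temperature structure the features are supposed to
measure.

## The 126-feature scheme

Each station-day-cultivar row carries:

| group | count | definition |
|---|---|---|
| daily descriptors | 4 | tmax, tmin, daily mean `(tmax+tmin)/2`, diurnal range |
| cumulative descriptors | 7 | Utah chill, North Carolina chill, chill hours in (0, 7.2] °C; growing degree hours above 0/4/7/10 °C — all season-to-date sums |
| forward EWMA | 30 | recursive EWMA of the daily mean, spans 1–30 days, `alpha = 2/(span+1)` |
| reverse EWMA | 30 | the same recursion run from the current day back to season start, so the earliest days weigh most |
| cultivar indicators | 54 | one-hot over the registry (21 *V. vinifera*, 33 hybrid) |
| days in season | 1 | days elapsed since the season start (start day = 0) |

The Utah and North Carolina chill models are stepwise hourly weight tables
(both turn negative at warm temperatures, so those two accumulations can
decrease; chill hours and degree hours cannot). Degree hours use the linear
`max(0, T − base)` form. Where a published scheme leaves room — the exact
identity of the four daily descriptors, the 30 spans, the chill-hours
convention — the defaults above are explicit, documented choices exposed in
`feature_config()` (spans as a 30-element list, replaceable chill weight
tables), and the structural identity 4 + 7 + 30 + 30 + 54 + 1 = 126 is
asserted on every emission. The reverse EWMA is computed by a closed-form
prefix recurrence (`alpha * S[t-1] + (1-alpha)^(t-1) * x[t]` with
`S` the decayed prefix sum), which the tests check against an explicit
per-prefix recursion for all 30 spans.

The bundled cultivar registry (`cultivars_synthetic.csv`) is a synthetic
stand-in: real cultivar names with plausible species classes, assembled for
this package. Swap in your own registry via `cultivar_registry(file=)`; only
the 21/33 class split is asserted.

## The LT50 regressor

`train_lt50_model()` fits a gradient-boosted tree ensemble (xgboost,
squared-error objective, single thread) with fixed documented defaults:
600 rounds, depth 6, learning rate 0.1, no subsampling. A held-out fraction
(default 10 %) is reserved by a seeded draw before fitting and scored
afterwards; the bundle records the seed, hyperparameters, feature names and
held-out RMSE, and `predict_lt50()` refuses feature tables whose columns do
not match the recorded names. Raw predictions are clamped to a
physiological band (default [−40, 0] °C). Feature attribution uses
permutation importance on the held-out rows — the mean RMSE increase over
seeded shuffles of each column — rather than any model-specific attribution,
keeping the model contract fully pluggable: anything with a train/predict
pair and a seed slots in behind the same interface.

Boosted trees were chosen over a stacked multi-model ensemble deliberately:
at the data scales this package targets (thousands of rows of synthetic or
single-network observations) a single well-tuned ensemble reaches the noise
floor, trains in seconds, and is reproducible bit-for-bit from one seed.

## Damage potential

The damage score is the logistic
`D = 100 / (1 + exp(k (tmin − LT50)))` with `k = ln(9)/2 ≈ 1.0986`, the
unique logistic slope satisfying both anchor conditions — 10 % potential at
2 °C above LT50 and 90 % at 2 °C below (odds multiply by 9 per 2 °C).
Symmetry (`D(tmin) + D(2·LT50 − tmin) = 100`), strict monotonicity in both
arguments, and the anchors to 1e-9 are all tested. Each day is scored
against the same day's tmin and the same day's predicted LT50. Other
symmetric sigmoids could satisfy the two anchors; the logistic is the
conventional dose-response choice and needs no additional shape parameter.

## Climatology

`season_summary()` reduces a season to its minimum temperature, its deepest
hardiness and its maximum daily damage. "Maximum cold hardiness" is read as
deepest hardiness, i.e. the most *negative* LT50 — hardiness language in
this field counts magnitude, but the numeric reduction must pick the
minimum. `window_average()` means those summaries per station over year
windows (defaults 1960–1979, 1980–1999, 2000–2024; the last is 25 years —
means are per-season, so unequal widths are fine). `knn_grid()` estimates a
regular grid as the unweighted mean of the k nearest stations (default
k = 5) under haversine distance, ties broken by station id; every cell value
is therefore a convex combination of station values, which bounds the grid
by the station range. `feasible_area()` weights cells by cosine(latitude)
when converting cell counts to area and reports the share below a damage
threshold (default 20 %) plus the percent change of each window against a
baseline. No land/sea mask is applied: the fractions are shares of the
gridded box, not of land. k, the 0.5° default resolution, and the metric are
declared configuration, not estimates of any published analysis's settings.

## Synthetic fixtures

The weather generator produces a seasonal sinusoid (minimum at the coldest
day: mid-January north, mid-July south) plus stationary AR(1) anomalies
(`phi = 0.7`, sd 3 °C by default), splits the mean into extremes by a fixed
diurnal range, applies independent per-day missingness, and encodes to the
fixed-width tenths-of-°C dialect. Defaults (annual mean 9 °C, amplitude
14 °C, range 8 °C) describe a continental mid-latitude station cold enough
for dormancy modelling to be interesting.

The LT50 truth model is expressed in the package's own features so that
recovery is a meaningful end-to-end check:

```
LT50_true = clamp( LT50_max + (LT50_min − LT50_max)·A + g·H + offset,
                   LT50_min, LT50_max )
```

with `A = min(1, chill_hours / chill_requirement)` the acclimation state,
`H` an EWMA (span 7 days) of daily degree-hours above 10 °C, `g` the
deacclimation gain (0.1 °C per smoothed degree-hour) and a per-species
offset (+2 °C for *V. vinifera*: less hardy). Heat enters with a positive
sign — deacclimation *raises* LT50 toward the ceiling — which is what
produces the U-shape: autumn chill pulls the curve down to the floor
(−28 °C) once the 800-chill-hour requirement saturates (midwinter at the
default generator climate), and spring heat lifts it back. The observed
series adds seeded Gaussian noise (default σ = 1 °C). This is a test
harness: it shares the *shape* of real hardiness dynamics, not calibrated
physiology, so passing recovery tests demonstrates that the pipeline
extracts and models the signal it defines — not that it predicts real vines.

## Problem sizes and numerical choices

The test suite and acceptance script run everything on one synthetic
station-network at desk scale: an 8-year record (seven curated seasons, two
cultivars, ~3 400 feature rows), training on 2 000 rows, gridding 20
stations onto 100 cells. At those sizes the noiseless-linear pilot fit
reaches held-out RMSE ≈ 0.02 °C (bound 0.5 °C) and σ = 1 recovery lands at
1.15–1.26 °C across seeds, inside the [0.8, 1.5] °C bracket implied by a
10 % hold-out of the injected noise. Ties in KNN distance are resolved by
station id so results are permutation-invariant; the EWMA recurrences
underflow gracefully for long seasons (decay factors reach 0 harmlessly);
physically inconsistent days (tmax < tmin) are blanked with a warning at
parse time rather than silently reordered.

## Known limitations

* Real GHCNd records fail in ways the generator does not model (multi-month
  outages, sensor drift, flag-worthy values); the quality-flag rule —
  any non-blank QFLAG invalidates the value — is conservative by design.
* The hourly curve is an idealisation; cold-air drainage, fronts and cloud
  cover produce days it cannot represent. The contract is the stated curve
  properties, not agreement with any particular hourly dataset.
* Trained surrogates extrapolate poorly outside the climate envelope of
  their training features — clamping hides, but does not fix, this.
* Feasible-area fractions have no land/sea or terrain masking and inherit
  the KNN grid's convexity: sharp spatial structure between stations is
  smoothed away.
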