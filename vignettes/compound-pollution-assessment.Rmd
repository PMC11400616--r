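---
title: "Assessing PM2.5–O3 compound pollution: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing PM2.5–O3 compound pollution: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fine particulate matter (PM2.5) and surface ozone (O3) are the two air
pollutants with the largest documented health burden, and they are coupled:
both draw on NOx and VOC precursors, particulate loading modulates the
photochemistry that makes ozone, and falling NOx can *raise* urban ozone
through reduced titration. City networks therefore increasingly see
*compound* pollution — periods in which both pollutants exceed
health-based thresholds — and mitigation has to be planned jointly.

`copollution` implements the complete desk workflow for such an
assessment on daily city-level monitoring series: quality control and
quota-gated aggregation, a four-class compound-pollution typology, trend
testing, a six-type exposure-risk typology, bivariate spatial association,
and a four-quadrant classification of synergistic change. This vignette
records the model assumptions, the tunable parameters and their defaults,
and the design decisions taken where the methodology was genuinely open.

## Quality control and aggregation

Daily concentrations are in µg/m³ throughout; no ppb conversion or
imputation is performed.

* **Row-level rules.** Values > 999 µg/m³ (strictly; 999 itself is kept),
  negative values and non-finite values are *flagged*, never altered;
  unparseable dates and unknown pollutant codes drop the row into the QC
  report; duplicated (city, pollutant, date) records collapse to the mean
  of their valid values with a warning. The QC report reconciles all
  counts: input rows = output rows + dropped rows + collapsed duplicates.
* **MDA8 ozone.** When hourly data are available, the daily O3 metric is
  the maximum of the 24 rolling 8-hour means that *end* in the calendar
  day, i.e. the first seven windows reach back into the previous day's
  tail. A window computes when ≥ 6 of its 8 hours are valid; the day is
  valid when ≥ 18 of the 24 windows compute. When no previous-day tail is
  supplied only the 17 fully in-day windows exist and the same 75% quota
  applies pro rata (≥ 13 of 17). With daily inputs (the common exported
  format) the step is bypassed and daily values are taken as-is. Whether
  an "annual O3 mean" should average daily MDA8 or some other daily metric
  is not standardised; we average daily MDA8 and state it here.
* **Quotas.** A monthly mean is valid with ≥ 27 valid days, an annual mean
  with ≥ 360 valid days (kept at 360 in leap years — the quota is a single
  stated number), a seasonal mean when all three member months are valid,
  and the study-period mean is the mean of valid annual means, valid only
  when every study year is valid. Invalid aggregates are carried with
  `is_valid = FALSE`, never silently imputed.
* **Seasons.** Meteorological three-month blocks (DJF/MAM/JJA/SON), with
  December assigned to the *following* year's winter. Labels are
  hemisphere-aware by default (southern-hemisphere cities shift by six
  months), so "winter PM2.5 peak" is meaningful in Sydney as well as in
  Beijing; `hemisphere_aware = FALSE` forces northern-calendar labels.

## Compound-pollution typing

With thresholds ρ(PM2.5) = 35 µg/m³ and ρ(O3) = 100 µg/m³:

| PM2.5 | O3 | label |
|---|---|---|
| > 35 | > 100 | `P-O` (compound) |
| > 35 | ≤ 100 | `PM25_dominated` |
| ≤ 35 | > 100 | `O3_dominated` |
| ≤ 35 | ≤ 100 | `Clean` |

The source classification writes strict inequalities on both sides, which
leaves exact equality unassigned; we close the boundary into the
lower-severity side (35/100 exactly → non-exceeding), a measure-zero
decision made once for reproducibility. The thresholds are daily-scale
criteria, while city labels are period-level; the period rule the
city-level results require is not uniquely determined, so both readings
ship: the default applies the rule to period means
(`mode = "mean"`), and `mode = "exceedance"` labels each day and calls a
pollutant "exceeding" when at least `exceedance_frac` (default 0.5) of
paired valid days exceed. The same ambiguity applies to seasonal shares;
the mode flag covers both.

## Mann-Kendall trend analysis

The test statistic, tie-corrected variance, and continuity-corrected
standardization are implemented exactly as defined (see README for the
formulas); two-sided tiers use |Z| ≥ 1.645 / 1.960 / 2.576. Design
decisions:

* **Input resolution.** The temporal resolution fed to the test is
  genuinely open. Default: *monthly valid means* over the study window
  (n ≈ 48), which comfortably satisfies the large-sample condition
  (n > 10) and damps daily autocorrelation; `annual` (n = 4, small-sample
  warning) and `daily` modes are selectable. Missing months are dropped —
  the test is rank-based and tolerates gaps — not imputed.
* **Direction gating.** For the risk typology, direction is the sign of Z
  regardless of significance (the typology speaks only of increasing /
  decreasing); `require_tier` optionally gates direction on a tier, in
  which case non-significant trends count as flat.
* **Degenerate input.** An all-tied series has Var(S) = 0; Z is defined
  as 0 with direction `none`.
* No Sen's slope and no seasonal/prewhitened variants: possible
  extensions, not part of this workflow.

## Exposure-risk typology

Bands per pollutant: PM2.5 low < 25, high 25–35, extremely high > 35;
O3 low < 100, high 100–120, extremely high > 120 µg/m³. Band edges are
written with strict inequalities on both sides in the source criteria and
are closed into the middle band. (Note the documented inconsistency
inherited from the source: O3 uses 100 as the typing threshold but 120 as
the extremely-high band edge; both are implemented as printed, not
reconciled.) Crossing band with trend direction yields HR, ST, R, DST, S,
HS; a flat trend (Z = 0) maps to the decreasing side with an explicit
`flat` flag — the six-cell scheme has no neutral cell, and flagging keeps
the partition total without hiding ties. The banding mean is the
study-period mean of valid annual means, matching the multi-year framing
of the assessment. Combined labels put PM2.5 first (`"ST + HR"` = PM2.5
extremely high falling, O3 extremely high rising). Population totals per
combined label conserve the grand population of labeled cities; cities
without population are excluded with a count.

## Spatial association

* **Weights.** k-nearest-neighbour (default k = 5) under great-circle
  distance, row-standardized to 1/k, deterministic tie-break by
  (distance, city id). The source analysis used GUI defaults without
  naming a scheme; kNN guarantees no islands among scattered world cities
  and k is configurable.
* **Bivariate Moran's I.** Variables standardized with the population
  (1/n) variance; local `I_i = c·x_i·Σ_j w_ij y_j` with the
  proportionality constant c fixed at 1 (the constant is never assigned in
  the source; 1 matches common LISA practice); global I = mean of local
  values — whether a printed global value is the matrix form or the mean
  of locals is unknowable without the original data, and for
  row-standardized weights these coincide here by construction. Cluster
  quadrants HH/LL/LH/HL come from the signs of standardized x and the lag
  of standardized y. Inference is by conditional permutation (x_i held
  fixed, neighbour values of y drawn from the other locations), default
  999 seeded draws, one-sided on the observed sign (the GeoDa
  convention). The sign-conditional pseudo p folds the null distribution
  onto (0, 0.5]; calibration checks therefore use the fixed upper-tail
  variant (`alternative = "greater"`), which is uniform under the null.
* **Local correlation.** The per-city "correlation surface" is a
  geographically weighted Pearson correlation: pooled (PM2.5, O3) annual
  pairs over the city and its neighbours, bisquare kernel on an adaptive
  bandwidth of b nearest cities (default 20). At full uniform bandwidth
  every local value equals the pooled global r (a tested limit). Whether
  the co-pollutant "correlation" of such an assessment is spatial or
  temporal is ambiguous, so both readings ship: the geographically
  weighted one (default, matching the GW-statistics toolchain the source
  cites) and `temporal_correlation()`, the within-city Pearson
  correlation of paired daily values.
* **Curvature.** OLS of local_r on (PM2.5, PM2.5²); the fitted peak
  −b/(2a) is reported only when the quadratic coefficient is negative
  beyond numeric noise (`-sqrt(eps)`), so exactly-linear data report no
  peak rather than a spurious one.
* **Precursors.** Emissions-vs-concentration association reuses the same
  two statistics unchanged (pure delegation, tested as such).

## Synergy quadrants

`ROC = C_end/C_start` on endpoint annual means (endpoint years are
config-driven, defaulting to the first and last valid study years — the
formula is unchanged, the years are not hard-coded). ROC = 1 exactly
counts as increase, per the "≥ 1" in the quadrant definition. A start-year
mean of 0 excludes the city with a log entry. Quadrant shares and
per-quadrant mean percent changes `(ROC − 1)·100` summarise the network.

## The synthetic stated world

The generator emulates the statistical structure of a 120-city, 4-year
(2019–2022) daily panel. Daily value = group baseline + linear trend +
cosine seasonality (month resolution; PM2.5 peaks January, O3 July,
southern-hemisphere cities flipped by six months) + Gaussian noise
(sd 5 µg/m³), truncated at zero; gross outliers are injected uniformly in
(1000, 2000] µg/m³ so the QC threshold can find all of them. Coordinates
cluster around continental centroids (scatter 1200 km), which is what
gives the spatial statistics a genuine signal; emissions are affine in the
planted city means plus lognormal noise, so zero coupling means
independence and zero noise means correlation exactly 1.

Six groups plant the composition: 10 Delhi-like hotspots (PM 150 falling
5/yr, O3 130 rising 3/yr → `ST + HR`), 47 compound cities (60/120,
−3/−8 per yr), 30 PM-dominant European-like cities, 2 ozone-dominant, 16
clean-improving and 15 clean-worsening cities — i.e. 57/120 (47.5%)
compound, 63/120 (52.5%) with both trends falling, magnitudes taken from
the printed city-level ranges of the motivating assessment. These are
stated-world constants, not tuning knobs.

Two generator parameters were constrained by internal consistency rather
than free choice: the default missing-day and outlier rates are 0.3% and
0.1%. Higher rates (e.g. 5% missingness) are incompatible with the
360-valid-day annual quota — *no* city-year would ever be labelable —
whereas the real study selected cities with complete series. The defaults
make the quota bind occasionally (a few city-years drop, exercising the
exclusion accounting) without gutting the panel; larger rates remain
available and are exercised in tests as explicit configs.

What the generator does *not* emulate: real station layouts, meteorology,
chemistry, autocorrelated daily noise, or non-monotone trends. A green
recovery test therefore establishes that the pipeline's label algebra and
statistics are correct on data with known structure — not that the
generator's world is a faithful atmospheric model.

## Numerical choices and degenerate inputs

* Standardization for Moran uses the 1/n variance; zero-variance input is
  an error (the statistic is undefined), as is a singular curvature
  design.
* Weighted Pearson requires ≥ 3 effective (positive-weight) pairs, else
  NA with a log count; values lie in [−1, 1] by construction, never
  clipped post hoc.
* Pseudo p-values use the (hits + 1)/(n_perm + 1) convention, capped
  at 1; permutations are seeded, so the full pipeline is byte-identical
  across runs at a fixed config.
* All boundary closures (35/100 typing equality, 25/35/100/120 band
  edges, ROC = 1) are fixed as documented above and asserted in tests.

## Known limitations

* Monthly Mann-Kendall input still carries some seasonal structure;
  within-year seasonality cancels pairwise for complete years, but
  partial years can bias S slightly. No seasonal-MK variant is provided.
* The annual quota keeps 360 in leap years, marginally stricter per
  available day.
* Great-circle kNN ignores coastlines and population surfaces; it is a
  neighbourhood model, not an exposure model.
* Quadrant and share statistics are unweighted city counts; population
  enters only through the exposure-risk totals.
* The acceptance calibration bands (type-I error in [3.5%, 6.5%] at 1,000
  replicates; KS p > 0.01 at 500 replicates) are Monte-Carlo statements
  and fail with the corresponding small probability under an unlucky
  seed; they are not tightened or reseeded to pass.
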