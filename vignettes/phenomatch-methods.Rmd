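---
title: "Camera-satellite phenology intercomparison: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-satellite phenology intercomparison: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomatch)
```

## The problem

Networks of fixed digital cameras record vegetated scenes every half hour
through the growing season. From the mean red/green/blue digital numbers
over a region of interest (ROI) of one vegetation type, canopy greenness is
summarised by the green chromatic coordinate,
$G_{cc} = G_{DN}/(R_{DN}+G_{DN}+B_{DN})$, a ratio that is robust to
illumination changes because the three chromatic coordinates always sum
to 1. Satellites observe the same landscapes at ~500 m resolution, and
phenology products report "greenup onset" and "dormancy onset" dates per
pixel. The two instruments measure different things — a camera footprint of
one vegetation type versus a mixed half-kilometre pixel — so quantifying
when and why their transition dates agree requires a pipeline with explicit,
testable stages. `phenomatch` implements that pipeline, together with a
synthetic-scene generator so every stage can be validated against known
truth.

## Camera greenness processing

Per-image samples are screened before any aggregation: the sun must be at
least 10 degrees above the horizon, and the mean digital number must lie in
a configurable brightness band (default 30-230) so under- and over-exposed
frames are dropped. Solar elevation uses the NOAA general solar-position
approximation (geometric, not refraction-corrected: near 10 degrees,
refraction is ~0.1 degrees, far below the screen's needed accuracy; the
implementation is good to a few tenths of a degree). Timestamps must carry
an explicit time zone — a silently mis-zoned timestamp moves the sun by 15
degrees per hour, so naive date-times are rejected rather than guessed.

Screened Gcc values are aggregated to one value per day with a centred
3-day moving window and one of four statistics: the mean or the 50th, 75th,
or 90th percentile. Percentiles interpolate linearly between order
statistics (`stats::quantile` type 7); the convention is stated because
different percentile definitions move 3-sample windows noticeably. A
`binned` mode with fixed consecutive 3-day bins, the layout of released
camera products, is available alongside the default sliding mode. The
best statistic for a site is chosen as the one whose spline fit (below) has
the lowest residual variance, with ties broken mean > p90 > p75 > p50.

## Spline smoothing and outlier rejection

The seasonal trajectory is a cubic smoothing spline whose flexibility is
selected by AIC,
$$\mathrm{AIC} = n \log(\mathrm{RSS}/n) + 2\,\mathrm{edf},$$
with the effective degrees of freedom equal to the trace of the smoother
matrix. The candidate grid is 14 log-spaced values from 4 up to
$\min(n_x - 2,\ 48\,\mathrm{years})$ equivalent degrees of freedom — the
flexibility a seasonal cycle needs is per year, so the ceiling scales with
the series span, and the spline's knot count is set to 2.5 times the
largest candidate so the smoother can actually reach it. A constant series
short-circuits to a degenerate exact fit.

Outliers — overwhelmingly cloud, fog, or snow frames that depress
greenness — are flagged iteratively: points whose residual exceeds
$k = 3$ robust standard deviations (1.4826 MAD) are removed and the spline
refit, up to 5 times. Two guards matter in practice. An absolute deadband
(0.005 index units, half the smallest outlier magnitude the generator
injects) prevents flagging in near-noiseless series, where the robust scale
collapses and 3-sigma would flag smooth-residual tails. And if a single
pass would flag more than 30% of the series the procedure aborts with a
warning: that is a degenerate fit, not contaminated data.

The pointwise 90% confidence envelope is
$\hat f(x) \pm z_{0.95}\sqrt{\hat\sigma^2 \ell(x)}$ with $\ell$ the
smoother leverage, interpolated between observation days when the envelope
is evaluated on the daily prediction grid. A bootstrap envelope was
considered and not implemented: the leverage-based envelope is exact for
the fixed-smoother Gaussian model, and its only role is to turn vertical
uncertainty into date uncertainty at threshold crossings.

## Phase segmentation

Greenness-rising and greenness-falling phases are parsed with PELT (Pruned
Exact Linear Time) applied to the first differences of the fitted curve on
a daily grid, with a Gaussian mean-shift segment cost
$C(s) = \sum x_i^2 - (\sum x_i)^2/|s|$ and penalty $3\log n$ per
changepoint. The differences are standardised by their SD before
segmentation, which makes the segmentation — and hence all transition
dates — exactly equivariant under affine rescaling of the greenness axis.
The search is exact: the package's optimal-partitioning recursion with the
standard pruning inequality (valid with $K = 0$ for this cost), and an
exhaustive no-pruning dynamic program is exported as
`optimal_partition_dp()` purely as a verification oracle.

Segments are labelled rising or falling by the sign of their mean first
difference and adjacent same-direction segments are merged. Each boundary
between merged phases is then refined to the local extremum of the fitted
curve between the two segment midpoints: physically a rising-to-falling
boundary is the seasonal peak, while a mean-shift changepoint on the
differences can sit a few days down-slope, which would truncate the phase
amplitude.

## Transition dates and their uncertainty

Within each phase the seasonal amplitude is the difference between the
phase's plateau and dormant levels, and the transition dates for fractions
0.10, 0.25, 0.50 are the first crossings (linear interpolation between
daily fitted values) of `dormant + fraction * amplitude`, in the phase's
direction. The first-crossing rule matches the notion of a transition
onset; a last-crossing variant is available.

The dormant and plateau levels are estimated robustly as the median of the
fitted curve over the lowest and highest tenth of its range within the
phase, rather than the raw pointwise minimum and maximum. The raw extremes
ride the spline's wiggle minima over the long flat dormant season: at the
package's reference noise level they sit ~2 wiggle-SDs low, which drags the
10% threshold down and biases rising dates ~2 days early and falling dates
~2 days late. The median-of-tail levels are unbiased for curves with flat
tails, leave noiseless extraction unchanged, and preserve affine
equivariance. For phases without flat tails (a pure ramp) they shift
thresholds slightly toward the interior; for seasonal greenness
trajectories, which plateau in both winter and midsummer, this is the right
trade. Phases whose amplitude falls below `min_amplitude` (default 0.02
index units, configurable) yield no dates at all — the gate that keeps a
muted drought year from producing false transitions, at the documented cost
of missing genuinely anomalous seasons.

Date uncertainty converts the spline envelope horizontally: the 90%
interval runs between the crossing dates of the upper and lower envelope
curves with the same threshold level. If an envelope curve never reaches
the level inside the phase the bound is clipped to the phase edge and
flagged. Dates are real-valued day of year, 1-based; multi-year series are
fitted on a continuous day axis so phases may straddle year boundaries, and
the year is carried alongside.

## Satellite quantities

NDVI is computed from red (band 1) and NIR (band 2) nadir reflectances as
$(b_2-b_1)/(b_1+b_2)$, missing when the band sum is non-positive. Each
16-day composite value is stamped with its period's first day — a
documented convention, since composite products do not pin their value to a
unique day. The 3x3-pixel window around the camera yields a per-date
min/max/centre envelope (the landscape-heterogeneity display) and a
majority IGBP landcover code, excluding masked cells; ties are reported as
unresolved rather than resolved toward any class, and the caller decides.
Satellite transition dates are ingested, not derived — the satellite
phenology algorithm is a product upstream of this package — and ingestion
accepts at most two phenological cycles per pixel-year, preserving both.

## Pairing and agreement statistics

A camera date pairs with a satellite date of the same site and direction
when their separation is under 90 days, one-to-one, greedily by smallest
absolute separation (the multiplicity rule matters only for double-cycle
years, where greedy matching by closeness is the least surprising choice).
Separations use a continuous calendar axis, so a December camera date can
pair a January satellite date. The difference is defined as satellite minus
camera: negative bias means the satellite date is earlier. For display and
per-phase statistics, rising dates after DOY 270 wrap to negative values
and falling dates before DOY 90 wrap past 365, keeping each phase's dates
on one continuous axis; the summary statistics are computed on wrapped
values by default (configurable).

Agreement per group is quantified by the pair count, per-source date SDs,
Pearson correlation, mean bias with SD, and an errors-in-variables (Deming)
regression with error-variance ratio $\lambda = \sigma_x^2/\sigma_y^2$:
$$b_1 = \frac{s_{yy} - s_{xx}/\lambda + \sqrt{(s_{yy} - s_{xx}/\lambda)^2
       + 4 s_{xy}^2/\lambda}}{2 s_{xy}}, \qquad b_0 = \bar y - b_1 \bar x.$$
Under this convention the slope increases monotonically with $\lambda$,
recovers the OLS slope of $y$ on $x$ as $\lambda \to 0$ and the reciprocal
OLS slope of $x$ on $y$ as $\lambda \to \infty$, and at $\lambda = 1$
minimises the summed squared perpendicular distances (orthogonal
regression). The discriminant is evaluated in a conjugate form when
$s_{yy} < s_{xx}/\lambda$ to avoid cancellation at extreme $\lambda$.
Slope and intercept standard errors are leave-one-out jackknife estimates —
distribution-light and robust to the mild heteroskedasticity of date
errors; slope tests against 0 and 1 use $t$ statistics with $n-2$ degrees
of freedom. A fit is *reportable* when the slope differs from 0 at
$p<0.05$ with $n \ge 10$; non-reportable Deming columns are blanked in the
summary table, which otherwise lists every (vegetation type) x
(apples/oranges) x (direction) cell and flags those with at least 25 pairs
in both phases as headline rows.

The regression error metric is the squared perpendicular distance
$d = (y - (b_0 + b_1 x))^2/(1 + b_1^2)$ — note this printed form is the
*square* of the geometric point-to-line distance, so the RMS distance
$\sqrt{\sum d_i/(n-2)}$ takes one square root and is in days. The
$n-2$ denominator treats the two regression parameters as consumed degrees
of freedom.

Vegetation-type representativeness uses the mapping AG {12, 14},
DB {4, 5}, EN {1, 5}, GR {10, 12, 14}: a pair is "apples to apples" when
the satellite pixel's IGBP code is in the camera ROI type's set, otherwise
"apples to oranges". Types absent from the table classify as oranges with
a warning.

## The synthetic generator: what it emulates, and what it does not

Seasonal cycles are product-of-sigmoid double-logistics,
$g(t) = b + A\,\sigma(r_u(t-m_u))\,\sigma(-r_d(t-m_d))$ — the standard
generative shape in land-surface phenology. True threshold dates come from
root finding on the noiseless curve and are the reference for all recovery
tests. Camera series add iid Gaussian noise and sparse downward outliers of
uniform magnitude 0.02-0.10 index units (clouds and snow depress apparent
greenness). Satellite NDVI per pixel is a convex mixture of component
vegetation signals across the 3x3 window (sub-pixel heterogeneity), sampled
every 16 days, and satellite transition dates are the centre-pixel
mixture's true dates plus Gaussian jitter of SD 5 d — the scale of typical
per-date uncertainty in transition-date products. Bimodal seasons (e.g.
grasslands with a summer dry-down) are supported by summing non-overlapping
cycles over a shared baseline; overlapping cycles are refused rather than
silently resolved.

Reference study conditions, used by the test suite and the acceptance
script: camera noise SD 0.005 index units and 2% outlier rate (chosen once
as visually realistic for midday ROI means — the real archives do not
publish a noise figure); cohorts of sites whose spring midpoints spread
with SD 20 d around DOY 130, autumn midpoints around DOY 270, amplitudes
0.08-0.15, rates 0.06-0.15/d, and within-site year effects of SD 8 d. The
baseline is a site (camera) property, constant across a site's years. The
across-site spread matters: correlation between camera and satellite dates
is driven by the ratio of date variance across site-years to per-date
error, so cohort statistics are only meaningful with realistic spread.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: snow-contaminated winter imagery with long correlated
artifacts, exposure drift and camera replacements, mixed-species ROIs whose
greenness is itself a mixture, satellite retrieval failures and multi-cycle
confusion, and any systematic camera-satellite date offset (the generator's
satellite dates are unbiased by construction, so end-to-end cohorts test
error propagation, not the field's real biases, which for actual archives
are of order one to three weeks depending on threshold and phase).

## Numerical choices and degenerate inputs

* AIC grid: 14 log-spaced df values; winner verified against the whole grid.
  RSS is floored at 1e-300 before the log; an interpolating fit therefore
  wins on noiseless data, which is the correct limit.
* PELT minimum segment length 5 d on daily grids (2 in the generic
  function); penalty default $3\log n$.
* Threshold crossings interpolate linearly between daily fitted values;
  sub-daily precision beyond that is spurious given the envelope width.
* Zero-sum colour triplets and zero-sum band pairs yield `NA`, never errors;
  downstream stages drop missing values explicitly.
* Degenerate Deming input ($s_{xy}=0$) errors with a clear message; $n<3$
  pairs refuse to fit; SDs are `NA` below $n=2$.
* Ties in landcover majority and unknown vegetation types never resolve
  silently (unresolved flag; oranges with warning).
* All simulation is seeded and restores the RNG state (`withr::with_seed`),
  so generation is bit-reproducible and composable.

## Problem sizes

The shipped checks run 100 synthetic site-years for recovery (20 sites x 5
years), 100 random series for the PELT/DP equivalence, 20-point Deming
fixtures, and 50 end-to-end cohorts of 10 sites x 5 years; these sizes give
stable aggregate statistics (600 recovered dates, 5000 pairs) while keeping
a full run in minutes on one core.

## Known limitations

* The AIC spline assumes roughly iid Gaussian residuals at the fitting
  resolution; heavily autocorrelated inputs (e.g. sliding-window means of
  dense sub-daily data) lead AIC to overfit. Fit at daily or binned
  resolution.
* The robust phase levels assume phases with flat tails; monotone ramps
  without plateaus get slightly interior thresholds.
* Jackknife SEs are first-order; for $n < 10$ they are noisy, which the
  reporting rule already screens out.
* The solar position is a low-cost approximation (a few tenths of a
  degree), adequate for daylight screening only.
* Only PNG imagery is read by the optional image front end; archival JPEG
  processing belongs upstream.
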