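---
title: "Methods: agreement of precipitation data sources in extreme-event exposure assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agreement of precipitation data sources in extreme-event exposure assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epeagree)
```

## The problem

Epidemiologic studies of precipitation and health assign a daily exposure to
an areal unit (typically a census tract or county) from one of three classes
of data: the nearest point weather station, a fine interpolated climate grid,
or a coarser model-assimilation grid. When the outcome of interest is an
extreme precipitation event (EPE) — a rare, thresholded event — these three
exposure pathways can disagree, and if the disagreement is patterned along
social-vulnerability lines it becomes differential exposure misclassification:
the very populations most vulnerable to climate hazards may be the ones whose
exposures are measured worst. `epeagree` implements that comparison end to
end: per-unit daily series from each source class, local EPE thresholds,
binary EPE classification, chance-corrected agreement (Cohen's kappa) pooled
and stratified by demographic and geographic factors, covariate-matched
subgroup comparisons, and station-proximity regressions — together with a
fully seeded synthetic data generator so the whole pipeline is testable
without touching external archives.

## EPE definitions

Two operational definitions are implemented:

* **Local percentile**: a day whose precipitation strictly exceeds the 99th
  percentile of that location's *wet-day* distribution. A wet day is a day
  with value strictly above `wet_min_mm` (default 0, i.e. any recorded
  precipitation); the cutoff is exposed because trace-precipitation
  conventions vary between networks.
* **Absolute**: a day with more than one inch (25.4 mm). "More than" is a
  strict inequality, and the percentile definition uses the same strict
  convention for consistency; a value exactly at its threshold is never an
  event.

Percentile thresholds use the linear-interpolation quantile convention
(type 7, the default in most statistical environments); the type is a
parameter since published recipes rarely state one. For station-based
exposure, thresholds are anchored to stations passing a 99% completeness
screen (evaluated *after* quality-flag removal — flagged days count as
absent) and each unit inherits the threshold of the nearest included station.
For gridded sources, each unit's threshold comes from its own area-averaged
series. Published recipes for gridded thresholds say "daily values" without
restricting to wet days while the station recipe restricts to "days with
precipitation"; we apply the wet-day restriction to **all** sources for
comparability, with `population = "all_days"` available to reproduce the
literal all-days reading.

## Exposure assignment

**Stations.** Each unit-day takes the value of the nearest station with a
clean, non-missing observation that day, so the assigning station can change
from day to day — deliberately the *simplest* station method, as commonly
used, rather than inverse-distance blending. Equidistant ties are broken by
lexicographic station id (deterministic and documented). The distance metric
is pluggable: planar Euclidean (km) for the synthetic region, great-circle
haversine (sphere radius 6371.0088 km) for lon/lat inputs.

**Grids.** Each unit-day is the area-weighted average of all cells contained
in or intersecting the unit polygon, with weights equal to exact
polygon-cell intersection areas (Sutherland–Hodgman clipping of the ring
against each rectangular cell plus the shoelace formula). When cells are
missing, weights are renormalized over the non-missing intersecting cells;
this choice is documented because published workflows rarely say. Hourly
products are first summed per pixel-day; a pixel-day with any missing hour
is missing.

**Proximity.** A unit's distance profile is the mean over days of the
distance from its centroid to the nearest *operating* station, binned as
0–7 km, 7–30 km (closed at both 7 and 30), and >30 km — the last band lying
at or beyond the radius of influence usually quoted for a single gauge.

## Agreement

For each two-way source comparison, unit-days are pooled into a single 2x2
table over complete pairs (unit-days missing in either source are dropped).
Cohen's kappa is

$$\kappa = \frac{p_o - p_e}{1 - p_e},$$

with observed agreement $p_o$ and marginal-product chance agreement $p_e$.
The standard error is the asymptotic large-sample variance of Fleiss, Cohen
and Everitt (1969) for two raters and two categories, with a normal 95% CI.
When chance agreement is 1 (both raters constant) kappa is undefined and
reported as such rather than clamped. Although some texts describe kappa as
ranging 0–1, the full range is $[-1, 1]$ and negative values are reported.
Landis–Koch labels use right-closed bands (<0 poor, 0.00–0.20 slight,
0.21–0.40 fair, 0.41–0.60 moderate, 0.61–0.80 substantial, 0.81–1.00 almost
perfect); since the bands are defined on two-decimal cut-points, banding
tolerates floating-point error of 1e-9 at the boundaries.

Pooling all unit-days into one table (rather than averaging per-unit kappas)
is the convention implied by continent-scale kappas with extremely narrow
CIs; a per-unit mode (`pooled = FALSE` in `stratified_kappa()`) is provided
for sensitivity analysis. Annual kappas restrict the pooled table to calendar
years; stratified kappas restrict it to unit strata.

## Vulnerability analyses

Units are stratified by: dichotomous majority flags (share strictly >50%);
income class (low income when the poverty share exceeds 20% — strict `>` by
default with a configurable `>=` operator, because published definitions
disagree between the two); SVI quartile bins, right-closed (very low
(0.00–0.25], low, high, very high); urbanicity; and the distance strata
above. Matched comparisons take a referent group (e.g. majority-Native
tracts) and split the remainder into units whose population density *and*
topographic prominence both lie within one sample (n−1) standard deviation
of the referent mean (closed intervals) versus the unmatched rest.
Topographic prominence is max − min elevation over cells intersecting the
unit, optionally after block-mean aggregation of the elevation raster.

Distance regressions are OLS fits of mean daily station distance (km) on
Native American share — entered as a proportion in [0, 1], so the
coefficient is km per unit share, the scale at which published coefficients
of ~27 make sense — then adding prominence and density (four model layouts).
One-way ANOVA compares unit characteristics across distance strata; the
degenerate zero-within-variance case reports an infinite F with p = 0 and a
note instead of erroring. Confusion counts (false positives/negatives of a
comparator against a reference source over a unit subset, total and per
tract) carry an explicit disclaimer that the reference is a comparison
anchor, not ground truth.

## The synthetic study region

The generator produces a square planar region (default 120 km side) tiled by
square tracts (default 8x8 = 64), with:

* **Truth field**: daily wet/dry occurrence from a thresholded Gaussian
  random field (exponential covariance, correlation length
  `spatial_range_km` = 30 km by default) with marginal wet probability 0.3;
  wet amounts gamma(shape 0.9, scale 8 mm) driven by a second correlated
  field so extreme days are spatially coherent. Dry cells are exactly zero.
  Fields are synthesized by circulant-embedding FFT, with negative embedding
  eigenvalues clamped to zero (the standard approximate remedy). Defaults
  give a mean wet-day amount of 7.2 mm and plausibly rare one-inch days.
* **Demographics**: racial/ethnic shares from a Dirichlet whose
  concentrations vary smoothly in space; poverty from a smooth logit; SVI as
  the percentile rank of a poverty+minority composite (uniform marginal by
  construction); density lognormal with urbanicity by density terciles. A
  shared smooth "remoteness" field raises Native American share, poverty and
  elevation together, emulating the empirical pattern that majority-Native
  tracts tend to be rugged, sparse, and high-vulnerability — this coupling is
  what makes the distance-regression recovery test meaningful.
* **Stations** (default 15): placed in tracts with probability proportional
  to `exp(-siting_bias * SVI)` (default bias 2), then uniformly within the
  tract. Outages come in geometric blocks (mean 10 days); roughly a third of
  stations are high-quality with a twentieth of the outage rate, so a 99%
  completeness screen keeps some stations and drops others by construction —
  mirroring real archives, where only a small fraction of gauges are
  near-complete. A small fraction of observed days (0.2%) carries a QC flag.
  Gauge noise is additive Gaussian (SD 0.5 mm, clamped at zero).
* **Derived products**: an interpolated fine product (inverse-distance
  weighting, power 2, of each day's available stations; exact at station
  cells) standing in for station-driven interpolation surfaces, and a coarse
  assimilation product (truth block-averaged 4x onto the coarse grid,
  mean-one lognormal multiplicative noise with log-SD 0.3, disaggregated to
  24 hourly layers by random simplex weights that sum exactly to the daily
  value).

A single seed fans out to per-stage child seeds by a counter scheme, so each
stage is individually reproducible and the whole region is byte-identical
under a fixed config.

**What the generator does not emulate**: real orography or storm tracks, the
actual interpolation/assimilation algorithms behind operational gridded
products, lon/lat geodesy (the region is planar), population-weighted
centroids, and seasonal cycles. Passing tests therefore demonstrate that the
*pipeline* behaves correctly and that injected vulnerability-siting effects
are recovered — not that any particular real data product has a particular
accuracy.

## Study conditions used by the checks

The test suite exercises the qualitative recoveries at fixed conditions
chosen once:

* **Stratified-agreement recovery**: 20 regions of 64 tracts, 12 stations,
  2 years, siting bias 3. A *moderate* bias matters here: with very strong
  bias all stations collapse into the least-vulnerable tracts and every
  other quartile becomes equally remote, flattening the kappa gradient
  between the upper quartiles; bias 3 spreads station density smoothly
  across the SVI gradient so mean agreement declines monotonically across
  quartiles, and the >30 km stratum sits clearly below 0–7 km.
* **Regression recovery**: 20 regions of 225 tracts (>=200 units), 110
  stations (about 0.5 per tract, the realistic continental gauge density,
  giving nearest distances of a few km), 1 year, correlation length 20 km on
  a 225 km region. Station density and the region-to-range ratio control the
  effective spatial degrees of freedom: with too few stations the
  nearest-distance surface is so smooth that OLS intervals are
  anti-conservative even with no injected bias. At these conditions the
  share coefficient is significantly positive in >=18/20 seeds under bias 6
  and its CI covers zero in >=18/20 seeds under bias 0.
* **End-to-end determinism**: the demo pipeline (16 tracts, 20 stations,
  2 years) is run twice and all output digests compared.

## Numerical and degenerate-input choices

* Quantile type 7; strict `>` exceedance everywhere; all-dry series raise a
  threshold-undefined error.
* Nearest ties broken by lexicographic station id; half-open grid-cell
  convention `[x, x+dx)`.
* Zero complete pairs in a kappa table is an error; an empty stratum or year
  is flagged `defined = FALSE` rather than erroring.
* Hourly disaggregation weights are normalized exponentials, so hourly
  layers sum to the daily value to machine precision (< 1e-9 mm is asserted).
* A day with no operating station anywhere fails interpolation loudly
  (degenerate network), while unit-days simply missing propagate as missing
  and are dropped pairwise downstream.

## Known limitations

Planar geometry only for the synthetic region (the haversine metric is
available for real lon/lat station/unit inputs, but grid aggregation assumes
a planar or equal-area frame); no event-duration or multi-day EPE
definitions; no weighted or multi-rater kappa; no mixed-effects models of
agreement over continuous modifiers (pooled stratification is the supported
tool); and OLS inference on spatially autocorrelated units is only
approximately calibrated — the regression-recovery conditions above were
chosen so that this approximation is adequate, and analysts applying the
package to strongly autocorrelated real data should consider spatially
robust errors.
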