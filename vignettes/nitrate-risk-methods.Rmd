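---
title: "Methods: deterministic and probabilistic nitrate risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deterministic and probabilistic nitrate risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrateRisk)
```

## The exposure model

Drinking-water risk from a single non-carcinogenic contaminant is assessed
in two steps. The estimated daily intake normalizes the ingested mass by
body weight,

$$\mathrm{EDI} = \frac{C_f \cdot C_d}{B_w} \quad [\text{mg/kg/day}],$$

with $C_f$ the nitrate concentration (mg/L), $C_d$ the daily water intake
(L/day) and $B_w$ the body weight (kg). The hazard quotient scales EDI by
the oral reference dose,

$$\mathrm{HQ} = \frac{\mathrm{EDI}}{\mathrm{RfD}},$$

with $\mathrm{RfD} = 1.6$ mg/kg/day for nitrate (US EPA IRIS). HQ is
dimensionless; values above 1 indicate exposure above the level considered
acceptable. The model is linear in $C_f$ and $C_d$ and inverse in $B_w$
and RfD — properties the test suite checks directly.

The four default groups span the intake-to-weight extremes of a drinking
population:

```{r}
default_exposure_groups()
```

Infants drink little per kilogram here (0.008 L/kg/day) because the
parameter set describes direct tap-water consumption, not formula
preparation; children are the critical group (0.057 L/kg/day), and indeed
every ordering test finds mean HQ children > teenager > adults > infant.

## The bundled survey and its errata

`iranshahr_nitrate()` returns the 66 published well measurements
(6.0–49.0 mg/L) from the Iranshahr survey;
`iranshahr_hq_reference()` returns the accompanying published per-sample
EDI/HQ table. Two deliberate choices:

- **Rounding.** Computation is in full double precision; comparison to the
  published 4-decimal values uses *decimal round-half-up*
  (`round_printed()`), because exact rational reconstruction of the
  published table shows ties such as 0.53125 printed as 0.5313. Under this
  rule all 264 EDI and 264 HQ cells reproduce exactly.
- **The summary rows.** The published per-column *Mean* and *SD* rows are
  internally inconsistent (both print 6.15 for concentration, and their
  EDI/HQ entries equal the formulas applied to 6.15, not the column
  statistics; the true concentration mean is 15.097, and —
  coincidentally — the true sample SD is 6.148). These rows are treated as
  an erratum: `summarize_risk()` recomputes mean, min, max and SD (sample
  convention, $n-1$) and the tests assert only the recomputed values and
  the exact Min/Max rows.

HQ exactly at the threshold is reported as *at* the acceptable limit, not
above it: `exceedance_flags()` and `prob_exceedance()` are strict
(`hq > threshold`). Negative or missing concentrations are rejected with
the offending sample named, never imputed.

## Monte-Carlo engine

`simulate_hq()` draws $n$ independent $(C_f, C_d, B_w)$ tuples from
per-input `dist_spec` distributions and evaluates HQ per draw through the
same arithmetic as the deterministic path (identical association, so a
point-mass configuration collapses *bitwise* onto `assess()`). Choices
that matter:

- **Which inputs are stochastic.** The surveyed data inform only the
  concentration, so the default is $C_f \sim$ lognormal fitted to the
  sample values, with $C_d$ and $B_w$ point masses at the group
  parameters; any input can instead be given a full distribution in the
  configuration.
- **Fitting.** `fit_concentration_dist()` fits each candidate family by
  maximum likelihood (`fitdistrplus`) and selects by smallest
  Kolmogorov–Smirnov statistic, ties broken by log-likelihood. On the
  bundled survey the lognormal (meanlog 2.652, sdlog 0.344) beats the
  normal, as expected for right-skewed concentration data. Degenerate data
  collapse to a point mass; the empirical distribution is the explicit
  fallback.
- **Iterations and seeding.** Default 10,000 iterations, the customary
  scale for this kind of probabilistic risk assessment. All randomness
  flows from the single configured seed through R's default Mersenne
  Twister; a fixed seed makes results bit-reproducible.
- **Physically impossible draws** (negative concentration, non-positive
  intake or weight) under untruncated specs are rejected and redrawn,
  counted on the result, and capped at 10× the iteration count before
  erroring — a guard against grossly misspecified inputs.
- **Percentiles** use linear interpolation between order statistics
  (type 7, the `stats::quantile()` default); the P90 is the value not
  exceeded in 90% of draws.
- **Sensitivity** is the squared Spearman rank correlation of each
  non-constant input with HQ, normalized to sum to 1 — the
  "contribution to variance" measure familiar from spreadsheet risk
  add-ins, chosen because rank-based measures are robust to the
  multiplicative model form.

The closed-form check used in the tests: with only
$C_f \sim \mathrm{Lognormal}(\mu, \sigma)$ stochastic,
$P90(\mathrm{HQ}) = e^{\mu + 1.2816\,\sigma} \cdot C_d / (B_w \cdot
\mathrm{RfD})$, and the simulated P90 must fall within three asymptotic
Monte-Carlo standard errors of it; the empirical mean must converge to
$e^{\mu + \sigma^2/2} \cdot C_d/(B_w\,\mathrm{RfD})$ at the $n^{-1/2}$
rate.

## IDW interpolation

`interpolate_grid()` predicts each cell-center value as
$\hat z = \sum_i w_i z_i / \sum_i w_i$ with $w_i = d_i^{-p}$ over the
selected neighborhood. Numerical and design choices:

- power $p = 2$ by default (configurable); weights are computed as
  $(d_{\min}/d_i)^p$ so very large powers cannot underflow and the
  $p \to \infty$ limit cleanly approaches nearest-neighbor prediction;
- a target within `exact_tol` ($10^{-9}$ degrees) of a sample returns the
  sample value, with coincident samples averaged — this keeps the
  interpolator exact at data points;
- distances are planar Euclidean in degree space (small-extent
  assumption, the common default for unprojected data); an
  equirectangular option scales longitude differences by
  $\cos(\bar\varphi)$ for wider extents;
- duplicate coordinates are averaged (with a warning) before
  interpolation, and samples without coordinates are dropped with a
  warning;
- rasters follow the ESRI ASCII convention: cell-center evaluation, rows
  north to south, `NODATA_VALUE` for cells with no sample inside the
  search radius.

Because normalized positive weights form a convex combination, every
prediction lies within the range of the input values — so a raster built
from survey-bounded wells can never spuriously cross the 50 mg/L
drinking-water guideline; `exceedance_mask()` exists for data that can.
Well coordinates were never published for the bundled survey, so the
spatial module is validated purely by properties on synthetic fields
(exactness, boundedness, translation invariance, the power limit) rather
than against a published map.

## Synthetic well networks

`generate_wells()` emulates the two features of real monitoring data the
pipeline relies on:

- **`random` mode** draws concentrations i.i.d. from a configurable
  distribution, by default the lognormal fitted to the bundled survey
  (meanlog 2.6518607, sdlog 0.3436157, frozen as package constants) — a
  right-skewed field on the realistic 6–49 mg/L scale.
- **`trend_plus_noise` mode** evaluates a smooth bilinear surface over
  the bounding box plus Gaussian noise (default SD 2 mg/L, the scale of
  combined measurement and short-range variability), floored at zero.
  The default coefficients span roughly 8–43 mg/L, mimicking a smooth
  regional gradient. The default extent is the approximate Iranshahr
  study area (60.5–60.9°E, 27.0–27.4°N); coordinates are uniform within
  it.

What the generator does *not* emulate: spatial clustering of wells along
settlements, correlated measurement error, censoring at detection limits,
or any hydrogeological transport structure. Passing the recovery tests
therefore shows the *pipeline* is consistent (fitting a 5,000-well sample
recovers the generating parameters within 5%; interpolating noise-free
trend wells recovers the surface with error shrinking as density grows),
not that real aquifers satisfy these assumptions.

## Problem sizes and numerical tolerances

The suite runs the full 66-sample reproduction exactly; Monte-Carlo tests
use 5,000–20,000 draws with fixed seeds, the convergence study uses 16
replicates at $n \in \{10^3, 10^4, 10^5\}$, and spatial property tests use
grids up to 20×20 over 15–800 synthetic wells — sizes at which every
stochastic tolerance (3–4 standard errors, ±0.05 on variance shares) has
comfortable statistical headroom. Stochastic assertions are all tied to
analytic error formulas rather than ad-hoc margins.

## Known limitations

- Ingestion of drinking water is the only exposure route; dermal and
  inhalation routes, multi-contaminant hazard indices and carcinogenic
  endpoints are out of scope.
- Monte-Carlo inputs are sampled independently; correlated inputs and
  variance-reduction schemes (Latin hypercube, quasi-random sequences) are
  not implemented.
- Kriging is deliberately not implemented; the spatial module is IDW
  only.
- The published probabilistic summary table for this survey (means around
  0.01–0.017 with P90 near 0.3 for every group) is inconsistent with the
  per-sample HQ scale it accompanies and cannot be reproduced from the
  stated inputs; the package reproduces its deterministic-vs-probabilistic
  *structure* (mean, SD, P90 per group) and leaves the printed numbers
  uninterpreted.
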