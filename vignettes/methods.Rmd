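---
title: "Decomposing canopy-height growth into temperature response, vigour and phase timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing canopy-height growth into temperature response, vigour and phase timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopytemp)
```

## The model and its assumptions

Stem elongation in winter wheat responds to ambient temperature almost
linearly over the range encountered in a temperate spring (interval means
stay well below 25 °C, where a linear approximation to the thermal response
is defensible).  The package therefore models the per-interval stem
elongation rate of a plot, `SER = ΔCH/Δt` in mm d⁻¹, as a straight line in
the mean interval temperature,

$$\mathrm{SER} = a\,T + b_{T_{crit}} + \varepsilon ,$$

and interprets the two coefficients as genetically distinct components:

* the slope *a* — how many extra mm per day one extra degree buys;
* the intercept evaluated at the critical temperature — the
  temperature-independent growth level, called *vigour*.

An ordinary regression intercept (at 0 °C) is an extrapolation far outside
the data and is strongly negatively correlated with the slope across plots;
an intercept at 20 °C is strongly positively correlated.  Somewhere between
the two the correlation crosses zero, and only there does the intercept
carry information orthogonal to the slope.  `scan_tcrit()` evaluates the
Pearson correlation between slope and intercept on a 0.01 °C grid from 1 to
22 °C and takes the grid point with the smallest absolute correlation,
per year, ties broken toward the lower temperature.  The correlation
numerator is `cov(a, b₀) + T·var(a)`, linear in `T`, so the curve is
continuous and monotone non-decreasing and the zero is unique; the closed
form `-cov(a, b₀)/var(a)` is kept in the package only as an analytic
cross-check (`closed_form_tcrit()`), the reported value is always the grid
scan.  If the sample covariance happens to put the zero outside the grid,
the nearest edge is reported with an `out_of_range` flag rather than
extrapolated.

Assumptions worth stating: growth within an interval is attributed to the
mean temperature of that interval (daily rates are averaged, which is exact
when the daily response is linear); regressions are per plot and unweighted,
with weak single-plot fits levelled out by replicates and years rather than
by weighting; negative SER records (measurement noise) are retained, since
discarding them would bias the slope.

### Phase timing

Phenology is timed in thermal units.  Growing degree-days accumulate from
the day after sowing as `max(T − base, 0)`; the base defaults to 0 °C, the
standard choice for wheat, and is configurable.  Normalized height
(percentage of final height) is linearly interpolated on the calendar axis
to daily values and then mapped through the thermal-time table — we
interpolate on days rather than directly on GDD because the measurements
are dated, not thermally indexed; under variable temperature the two differ
slightly.  `GDD_15` and `GDD_95` are the thermal times of the first upward
crossings of 15% and 95%; later noise-induced re-crossings are ignored.
Final height is the plateau of the series: the maximum height at or before
the first observation followed by `k_flat = 3` consecutive increments below
`tol_mm = 5` mm.  "Several consecutive measurements" is inherently a
judgement call; both knobs are exposed, and raising the tolerance can only
move the plateau earlier (a property the tests exercise).  The plateau
search starts at the steepest observed increment so that a flat
pre-shooting baseline is never mistaken for the plateau.  A series with no
plateau falls back to the maximum height and is flagged, not dropped.

The plot regression is restricted, by default, to intervals whose endpoint
heights lie between 15% and 95% of the detected final height — the same
proxies that delimit the phase traits.  Intervals before shooting or after
the plateau contain no elongation signal at any temperature; leaving them
in dilutes the slope toward zero by an amount that depends on each
genotype's timing, which would leak phase information into the response
traits.  `phase_only = FALSE` restores the regression over all intervals.

### Spatial correction

Field trials carry smooth fertility/moisture gradients and row/range
artefacts.  Following the two-stage practice for augmented designs, each
measurement date is corrected independently with a model
`value ~ genotype + f(row, range) + row + range`, where `f` is a
tensor-product P-spline surface (second-order difference penalties, knots
per axis at two-thirds of the number of rows/ranges, smoothing parameters by
REML with a GCV fallback, null space shrinkage enabled) and row/range are
ridge-penalized random effects; the corrected plot value is the genotype
estimate plus the residual.  This is a deliberately simplified surface
decomposition in the spirit of the PS-ANOVA spatial models used for such
trials, not a re-implementation of any particular package: the contract is
trend-recovery behaviour (an injected bowl must disappear from the
residuals; trend-free data must pass through unchanged), which is what the
tests assert.  Random-effect predictions are re-centred to sum to zero with
the shift folded into the genotype estimates, so the correction preserves
the grand mean.  Exactly noise-free inputs leave no residual information
for the field terms; the correction is then the identity by construction.

### Genotype-by-year analysis and heritability

Cross-year aggregation uses `y = μ + G + Y + GY + ε` on corrected plot
values, year fixed, GY random, restricted to genotypes present in every
year.  With genotype fixed the adjusted means are BLUEs; with genotype
random, REML (via `lme4`, bobyqa with tight convergence tolerances) yields
BLUPs and the components (σ²_G, σ²_GY, σ²_ε), negative estimates truncated
at zero.  On balanced data these coincide with the classical
expected-mean-squares ANOVA estimators, which the tests use as an
independent oracle.  Broad-sense heritability on a genotype-mean basis is

$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GY}/n_{years} +
\sigma^2_\varepsilon/(n_{years}\,n_{reps})},$$

with the divisors generalized to the design sizes; traits scored once per
season use the reduced form σ²_G/(σ²_G + σ²_ε/n_env).  An exactly
noise-free trait degenerates the mixed model (zero residual variance), so
the fit falls back to ordinary least squares with zero variance components
rather than forcing the optimizer through a singular fit.

The final-height model regresses genotype BLUEs of height on slope, vigour,
GDD_SE and 0/1 allele contrasts at *Rht-B1*, *Rht-D1* and *Ppd-D1* with all
two-way interactions, complete cases only.  Aliased terms are detected from
the coefficient vector, removed term-wise and reported by name; inference
is by type II ANOVA (each term adjusted for all others except interactions
containing it).  When the fit is numerically saturated the type II table is
built directly from nested-model residual sums of squares, where the
F-statistics are undefined and reported as `NA`.

## The synthetic trial generator

No plot-level data from the motivating field campaigns are redistributable,
so the package ships a generator whose defaults emulate their design:
~330 genotypes, two replicates in diagonally offset blocks of an augmented
grid, three seasons, 22 twice-weekly height measurements between days 177
and 253 after mid-October sowing.  Its purpose is to give every stage a
recoverable ground truth.

Generative law: inside a genotype's thermal window (start/end in GDD after
sowing) the latent daily height gain is `vigour + slope·(T − T_ref)` mm,
clamped at zero, integrated and capped at the genotype's final height;
outside the window it is zero.  Slope and vigour are drawn independently,
so `T_ref` (default 9 °C) is the generative critical temperature, matching
the definition of vigour.  Genotype-by-year deviations of slope, vigour and
window are shared by both replicates within a year; measurement noise is
additive Gaussian on each observed height.  The pre-elongation canopy sits
at 12% of final height, so the 15% crossing tracks the thermal onset
closely; the cap is set at 97% of the expected gain so that a plateau
reliably forms, which places the 95% crossing slightly before the thermal
end of the window — the same bias the proxy has on real data, and the
tests therefore check it against a day-loop oracle rather than naively
against the window end.  Optional allele effects lower vigour (*Rht*
dwarfing), advance the window start (*Ppd* insensitivity) and shift final
height directly, so the allele contrasts in the height model carry signal
that is not fully mediated by the growth traits.

Weather is an annual cosine phased on days after sowing (equal-length
seasons are then exactly comparable) plus AR(1) noise, with the level
anchored so the configured mean is the mean *over the measurement window*.
Defaults: 14 °C window mean, 8 °C seasonal half-range, lag-1
autocorrelation 0.6, marginal sd 3 °C, per-year level shifts of ±1 °C —
spring conditions under which interval means stay below ~22 °C.

Parameter magnitudes were chosen once to mimic the published trait
variances: genotypic slope sd 0.27 mm °C⁻¹ d⁻¹ with genotype-by-year sd
0.18, vigour sd 1.0 mm d⁻¹, elongation onset 1150 ± 35 °C·d, duration
560 ± 25 °C·d, dwarfing-allele frequencies 7% / 58% / 13%.  The measurement
noise default (2 mm) is the one free scale the source does not state; it
was calibrated once so that the simulated heritability of the slope lands
near 0.8 at full scale, and then frozen.  Under these conditions the
pipeline recovers genotype-level slope and vigour with correlations above
0.9 to the simulated truths — the recovery bar the tests enforce — and a
noiseless, deviation-free configuration recovers the growth law on every
plot to ≤ 1e-6 relative error.

What the generator does **not** emulate: the LIDAR point-cloud-to-height
extraction (heights are taken as given, noise is i.i.d. Gaussian rather
than canopy-structure dependent), lodging, missing plots, frost or drought
events, vernalization/photoperiod physiology, and any marker data beyond
the three major loci.  Passing tests therefore demonstrate that the
*estimators* recover a known data-generating process of the assumed form;
they cannot certify behaviour under model misspecification that real
canopies may exhibit.

## Problem sizes and numerical choices

The test suite runs the full pipeline at 300 genotypes × 2 replicates × 3
years for the recovery checks, 20 independent 300-genotype cohorts for the
variance-component study, and smaller cohorts (10–60 genotypes) for exact
and structural checks; these sizes keep each property statistically sharp
while the whole suite stays fast.  Other numerical choices: the T_crit grid
is fixed at 1–22 °C in 0.01 °C steps with no sub-grid interpolation
(matching the empirical scan it mirrors); interval temperatures average the
half-open interval (start, end] so each day is attributed exactly once;
plots whose regression preconditions fail (fewer than three intervals, zero
temperature variance) are excluded from the scan and reported, never
imputed; dates with insufficient coverage are skipped by the spatial
correction with a warning rather than corrected from too few plots.

## Known limitations

* The spatial stage is a stand-in with the same contract, not a numerical
  replica of published SpATS decompositions; effective dimensions and
  smoothing parameters are not comparable.
* T_crit is estimated per year from the plot ensemble; with few plots or
  little slope variance the scan is noisy, and the package reports the
  minimum-|r| grid point regardless (flagged when the zero lies outside
  the grid).
* Estimation error in slope and intercept is negatively correlated within
  a plot, which pulls the empirical T_crit slightly toward the mean
  measurement-window temperature relative to the generative reference —
  visible in the worked example's per-year values.
* `heading_GDD` enters only as supplied data (single replicate per season);
  the package never derives heading from height series.
* GWAS, kinship, linkage disequilibrium and candidate-gene annotation are
  out of scope; only the multiple-testing threshold rule is provided.
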