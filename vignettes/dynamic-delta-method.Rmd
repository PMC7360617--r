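---
title: "The Dynamic Delta Method: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Dynamic Delta Method: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodelta)
```

## The problem

Late-Quaternary macroecology needs climate fields that are simultaneously
long (the last glacial cycle, ~120,000 years), spatially fine (half a degree,
so that mountain ranges and coastlines matter), and consistent with modern
observations. General circulation model snapshots deliver the temporal
coverage but at coarse resolution and with systematic biases; high-resolution
simulations exist only for a handful of reference times; observational
climatologies exist only for the present. `paleodelta` implements the
two-stage procedure that combines all three.

## The model

Let $X(m, t)$ be a monthly climate variable ($X \in \{T, P, C, H, W\}$:
temperature, precipitation, cloudiness, relative humidity, wind speed) on a
coarse grid, for months $m = 1,\dots,12$ and snapshot times $t$ on a 72-point
axis $T_{120k}$ (2,000-year steps from 120,000 BP to 22,000 BP, 1,000-year
steps thereafter). A small set of high-resolution simulations exists on a
9-point sub-axis $T_{21k} = \{21000, 18000, 15000, 12000, 10000, 8000, 6000,
3000, 0\}$ BP.

**Stage 1 (Dynamic Delta Method).** For every reference time $\tau \in
T_{21k}$ the fine-grid correction term is

$$\Delta X(m, \tau) = X_{\mathrm{fine}}(m, \tau) - X^{\boxplus}(m, \tau),$$

where $\boxplus$ denotes Akima regridding of the coarse field to the fine
grid. The downscaled field at any $t$ is

$$X'(m, t) = X^{\boxplus}(m, t) + \sum_{\tau \in T_{21k}} w(t, \tau)\,
\Delta X(m, \tau),$$

with nonnegative weights summing to one. The weights are an inverse-square
distance interpolation in atmospheric CO$_2$, a first-order index of the
global climatic state:

$$w'(t, \tau) = \frac{1}{(\mathrm{CO_2}(t) - \mathrm{CO_2}(\tau))^2},
\qquad w = w' / \textstyle\sum_\tau w'.$$

When $\mathrm{CO_2}(t)$ coincides with the CO$_2$ of one or more references
the inverse-square form is singular; we define the weights by its continuous
limit, an indicator on the exact matches split equally among ties
(`co2Weights()`, relative match tolerance $10^{-12}$). In particular, at
$t \in T_{21k}$ stage 1 returns the high-resolution simulation itself — an
identity the test suite asserts to machine precision. The classical Delta
Method is the special case $w(t, 0) = 1$: a *fixed* modern correction term.
The dynamic variant lets the fine-scale heterogeneity (orographic gradients,
coastlines) vary with the climate state instead.

**Stage 2 (classical additive Delta Method).** Against a gap-filled modern
observational climatology $X_{\mathrm{obs}}(m, 0)$ on the target grid,

$$X'(m, t) = X^{\boxplus}_{\sim 1^\circ}(m, t) + X_{\mathrm{obs}}(m, 0) -
X^{\boxplus}_{\sim 1^\circ}(m, 0),$$

which removes the remaining model bias and makes the present-day output
identical to the observations.

**Capping.** Addition does not preserve physical bounds, so after each stage
values are clamped: precipitation and wind speed at 0, cloudiness and
humidity to $[0, 100]$ %; temperature is unbounded. Capping happens after
stage 1 and again after stage 2, never between months, and each field
carries a per-month diagnostic (count of capped cells, maximum exceedance)
in its metadata so the "capping touches only a few near-bound points" claim
is checkable on any run.

**Why additive and not multiplicative?** A multiplicative delta
($P \cdot \mathrm{obs}/\mathrm{sim}_0$, equivalent to an additive delta on
log-transformed data) guarantees nonnegativity but (a) locks any cell with
zero modern observation at zero forever, (b) blows up as the simulated
modern baseline approaches zero, and (c) is not self-consistent: the annual
sum of monthly deltas differs from the delta of annual sums.
`multiplicativeDelta()` exists purely as a comparator, flags zero-denominator
cells instead of zeroing them, and the suite exhibits all three failure
modes on constructed counterexamples while the additive form passes the
self-consistency check exactly.

## Annual temperature extremes

Monthly simulation output contains no diurnal information, so annual
minimum/maximum temperature is reconstructed from the coldest- and
warmest-month means: the past-minus-present anomaly of the coldest (warmest)
monthly mean is applied to observed modern annual extremes
(`reconstructExtremes()`). The underlying assumption — monthly-mean anomalies
track daily-extreme anomalies — is exactly recoverable in a constructed
world where it holds, and the test suite does so. Because the two anomalies
are applied independently, reconstructed min can exceed max where the
observed range is narrow; such cells are counted and reported, never
silently repaired, since repairing would hide a failure of the assumption.

## Bioclimatic variables

`deriveBioclim()` produces the 17 layers BIO1 and BIO4–BIO19 (BIO2/BIO3 need
diurnal range and are structurally unavailable). Quarters are circular
3-month windows; ties between equally extreme windows go to the earliest
start month, deterministically. Two estimator choices were genuinely open:

* **BIO4** is the standard deviation of the 12 monthly temperatures in °C.
  We treat the 12 months as the complete annual cycle (population form,
  divisor 12) by default, since the layer is a property of the cycle, not a
  sample estimate; sample-form and the WorldClim ×100 convention are
  available as options.
* **BIO15** is the coefficient of variation of monthly precipitation
  (population sd / mean, dimensionless), defined as 0 where the mean is 0;
  the WorldClim variant ($100\,\mathrm{sd}/(\bar{P}+1)$) is an option.
* **BIO5/BIO6**: some tabulations label BIO5 "minimum" and BIO6 "maximum"
  while defining BIO7 = BIO5 − BIO6 as max minus min. We resolve the
  contradiction in favour of the formula — BIO5 is the maximum — so BIO7 is
  nonnegative, and record the convention in the set's metadata.

Every layer is checked against a brute-force month/quarter enumeration
oracle on randomized climatologies.

## Numerical choices

* **Akima regridding.** The field-standard interpolant for climatologies is
  the Akima cubic Hermite: smooth, but without the overshoots of a global
  bicubic. The 1-D form is extended to 2-D as a tensor product — a latitude
  pass then a longitude pass, in that fixed order. Longitude is periodic:
  the axis is wrap-padded with 3 columns from the opposite edge (the Akima
  stencil is 5 points wide) so the dateline is seamless. Target latitudes
  beyond the source extent are clamped to the nearest source row, avoiding
  polar overshoot. The package carries its own `akima1()` implementation
  with the original ghost-point end conditions, validated against frozen
  values from an independent implementation and against the interpolant's
  exact cases (straight lines, node reproduction). When source and target
  grids coincide the regrid is the identity, which is what makes the two
  anchor identities hold to machine precision rather than merely to
  interpolation accuracy.
* **Gap filling.** Modern observations are terrestrial; at glacial sea
  levels, shelf cells need values. `idwExtrapolate()` fills invalid cells
  with inverse-square-distance weighted means of the k = 10 nearest valid
  cells (great-circle distances between cell centers). Power 2 matches the
  inverse-square convention of the CO$_2$ weighting; k is configurable. The
  fill is a convex combination, hence within the donors' range, idempotent,
  and never touches valid cells.
* **Land configuration.** Cells above the contemporaneous sea level are
  land; wet cells 4-connected (longitude wrap, no diagonals — conservative
  about straits) to an open-ocean seed are ocean; remaining depressions are
  inland-below-sea-level (Caspian-type endorheic basins) and keep their
  climate values under masking. The seed defaults to the deepest cell and
  is configurable, because no coastline dataset specifies which basins
  count as ocean. Lowering sea level can only move cells ocean → land,
  a monotonicity the suite checks.
* **Quantiles.** Validation summaries (median and quartiles of absolute
  model-proxy differences) use linear interpolation between order
  statistics (R type 7), fixed and documented; the oracle in the tests is
  an independent sort-based implementation.
* **Grids.** Cell-centered registration throughout: edges on integer
  multiples of the resolution, longitudes in (−180, 180], latitudes
  ascending and strictly inside (−90, 90). Misaligned ranges are rejected
  at construction.

## The synthetic world

Real inputs (multi-century GCM output, reanalysis climatologies, ice
reconstructions) are not redistributable at package scale, so every stage is
exercised on a seeded synthetic world (`makeWorld()`) whose statistical
structure mirrors the real constellation:

* a **truth** field = large-scale smooth component (zonal gradient, seasonal
  cycle with hemispheric phase, a planetary wave, a CO$_2$-tied global
  cooling) + an orography-linked fine-scale pattern whose amplitude
  $g(\mathrm{CO_2}) = 1 + a\,(280 - \mathrm{CO_2})/90$ depends on the
  climate state (default $a = 4$);
* the **coarse simulation** = block-aggregated truth + a fixed additive
  bias (amplitude 2 in variable units) — biased and unresolved, like a GCM;
* the **fine reference simulations** = truth + noise (sd 0.1) at the 9
  reference times;
* **observations** = the exact truth at $t = 0$ on the finest grid;
* a CO$_2$ curve oscillating between 190 and 280 ppm with a 41-kyr period,
  so the last 21 kyr span most of the full glacial-interglacial range — the
  premise that makes reference-time corrections transferable; a sea-level
  curve tied to CO$_2$ (−130 m at the minimum); zonal ice masks growing in
  glacials.

Grid sizes are 15°/5°/2.5° over latitudes within ±75°, preserving the
3× / 2× nesting of the real two stages at sizes where the full suite runs
in about two minutes; the recovery experiment below uses 20 worlds and 6
held-out times each. What the synthetic world does **not** emulate: real
spatial covariance structure, non-additive (state-dependent) model bias,
internal variability between the 30-year climatologies, and proxy age/
calibration uncertainty. Passing tests therefore demonstrate the
correctness and the internal logic of the method — the anchor identities,
bound handling, the superiority of state-dependent corrections when
fine-scale structure genuinely varies with state — not the realism of any
particular reconstruction.

## What the experiments show

```{r recovery, eval = FALSE}
re <- recoveryExperiment(nSeeds = 20)
mean(re$dynamicWins)                       # fraction of worlds where dynamic wins
mean(re$rmseDynamic / re$rmseFixed)        # typical RMSE ratio
```

On worlds with CO$_2$-dependent fine-scale anomalies, stage 1 with dynamic
weights achieves markedly lower held-out RMSE than the fixed modern
correction in essentially every seed (the acceptance script recomputes the
win fraction and ratio on every run). With the amplitude dependence switched
off (`fineAmp = 0`) the two coincide up to noise — the advantage is the
state dependence, not extra smoothing. The proxy-validation statistic is
calibrated against a known limit: with proxies = truth + $N(0, 1)$ noise,
the median absolute difference converges to $\Phi^{-1}(0.75) \approx
0.6745$, which the suite checks at $n = 10{,}000$ within 5 %.

## Known limitations

* The tensor-product Akima extension is axis-ordered (latitude, then
  longitude); a transposed order gives slightly different interior values.
  The order is fixed and documented rather than configurable.
* `idwExtrapolate()` is $O(\text{holes} \times \text{donors})$; adequate at
  0.5° global scale but not optimized beyond that.
* The ocean/inland distinction depends on the connectivity rule and the
  seed; 8-connectivity would open diagonal straits and is deliberately not
  offered.
* Observational baselines for different variables may come from different
  reference periods; the stage-2 formula is applied uniformly regardless,
  replicating standard practice.
* Ice-sheet overriding post-processes vegetation-model output; the
  vegetation model itself is external and out of scope.
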