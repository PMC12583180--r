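---
title: "Methods: vegetation-cover dynamics, terrain effects and driver attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vegetation-cover dynamics, terrain effects and driver attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic scenes do and do not emulate, and the numerical
decisions taken where the underlying conventions are genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## The raster substrate

Every stage operates on a minimal raster model: a numeric matrix with row 1
as the northernmost row, a pixel-center affine transform, and a nodata mask.
All layers of an analysis are assumed co-registered on one master geometry
(250 m cells by default); `align_resample()` provides nearest-neighbour and
bilinear resampling for bringing layers onto it, with nearest mandatory for
categorical layers (bilinear would invent class labels). The mask propagates:
any output cell whose inputs include a masked cell is masked, so fill values
can never leak into statistics.

Rasters are read and written in a plain-text CSV dialect (header lines with
shape, transform and nodata, then rows north to south). No GeoTIFF driver is
shipped: no raster I/O library is available in the target environment, and
the dialect keeps all fixtures diffable. Reprojection between coordinate
systems is out of scope; cell area is nominal (`dx * dy`), with no geodesic
correction — at basin scale in a projected CRS this is the convention the
area tables assume anyway.

Slope and aspect come from Horn's 3×3 finite differences. Aspect is the
compass direction the surface *faces* (downhill), degrees clockwise from
north; cells with slope below 0.5° get the conventional flat code −1. Border
cells are masked rather than padded.

Scattered climate-station-style inputs are gridded by inverse distance
weighting with the common GIS defaults (power 2, 12 nearest neighbours,
both exposed); a cell coinciding with a sample returns the sample value
exactly.

## FVC estimation

The dimidiate pixel model treats each pixel's index value as a linear
mixture of a pure-soil and a pure-vegetation endmember:
`FVC = (EVI − EVI_soil)/(EVI_veg − EVI_soil)`. Because truly pure pixels are
rare and endmember values drift with region and season, the endmembers are
estimated as the 0.5 % and 99.5 % cumulative-frequency percentiles of the
unmasked index values (linear interpolation between order statistics —
deterministic and standard). FVC is clipped to [0, 1]: pixels beyond the
percentile endmembers would otherwise leave the physical range.

Two conventions are genuinely ambiguous in the field and both are
implemented:

- **Annualisation.** The monthly maximum-value composites can be averaged to
  an annual index (the default, `annualize = "mean"`) or reduced to the
  annual maximum (`"max"`). The mean is the default because it is the
  quantity the grade and trend analyses downstream describe; the annual
  maximum emphasises peak greenness instead.
- **Endmember scope.** Endmembers are estimated per year by default
  (`endmember_scope = "per_year"`), making each year's FVC a relative
  measure against that year's own distribution; `"pooled"` uses one pair for
  the whole record. Per-year scope partially absorbs basin-wide shifts into
  the endmembers — on scenes with a planted block trend this shows up as a
  small opposite drift in the unchanged pixels. Parameter-recovery tests
  therefore score the trend engine on annual mean EVI, where the planted
  trend is defined; the FVC-level typology is tested for precision, not for
  slope magnitude.

Grades use lower-edge-inclusive bins `[0, .2), [.2, .4), [.4, .6), [.6, .8),
[.8, 1]`; the printed interval labels in the literature overlap at the
boundaries, so lower-inclusion (with the top bin closed) is adopted as the
single consistent rule.

## Trend and stability

The Theil–Sen slope is the median of all pairwise slopes; with an even pair
count the two central order statistics are averaged. The Mann–Kendall
statistic counts concordant minus discordant pairs; the default variance is
`n(n−1)(2n+5)/18`, the no-ties formula, because that is the stated
convention of the method chain being reproduced — a tie-corrected mode
(`tie_correction = TRUE`) subtracts `Σ t(t−1)(2t+5)/18` over tie groups and
is recommended when FVC rasters are quantised. `Z` carries the ±1 continuity
correction, which maps `|S| = 1` to `Z = 0`.

The five-class typology uses `|ρ| = 0.0005 FVC/a` and `|Z| = 1.96`. The
rule's published form does not cover the cell `|ρ| < 0.0005` with
`|Z| ≥ 1.96`; it is mapped to *stabilization*, reading the slope threshold
as the primary magnitude criterion (a trend too small to matter is not a
trend, however consistent its sign). Pixels with fewer than 3 usable years
are masked and counted.

The coefficient of variation is the sample standard deviation over the mean,
undefined (masked) where the mean is not positive; its five fluctuation
classes break at 0.07 / 0.17 / 0.30 / 0.50, lower-edge-inclusive.

Lagged climate correlations are per-pixel Pearson correlations between
FVC(year) and driver(year − lag), two-sided t-test with n − 2 df, requiring
at least 5 overlapping years. No prewhitening for serial autocorrelation and
no across-pixel multiplicity control are applied — deliberately, to match
the method chain being reproduced; significance maps must be read
accordingly.

## Transitions and terrain dominance

Transition matrices are pixel cross-tabulations scaled by nominal cell area;
pixels masked in either epoch are excluded, so successive matrices on a
fixed mask share their grand total (a tested conservation law). Derived
statistics are defined so they can also be run on a published matrix
directly: net change = column total − row total; outflow/inflow shares =
off-diagonal row/column splits; changed area = off-diagonal sum. When run on
the bundled published basin matrices, the recomputed 2001–2022 changed area
is 10 850.91 km², not the 11 130.56 km² printed alongside the matrix — the
published headline is inconsistent with its own table, and the package
reports the recomputed value.

The terrain distribution index `K = (S_ie/S_e)/(S_i/S)` compares a change
type's share inside a stratum to its basin-wide share. Its area-weighted
mean over strata is exactly 1 for every change type (an algebraic identity
the tests assert), so K values are read as relative enrichment. Elevation
strata are fixed at < 3500 / 3500–3800 / 3800–4200 / > 4200 m
(lower-inclusive); slope at 3 / 7 / 12 / 18°; aspect windows are resolved to
the symmetric half-degree-exact form (shaded [0, 67.5) ∪ [337.5, 360),
semishaded [67.5, 112.5) ∪ [292.5, 337.5), semipositive
[112.5, 157.5) ∪ [247.5, 292.5), sunny [157.5, 247.5), flat = −1), since the
published windows mix 337 and 337.5 and would otherwise overlap.
`jenks_breaks()` (exact Fisher dynamic programming, compiled) can re-derive
data-driven elevation edges; the fixed values remain the default scheme.

## Geodetector

The factor detector is `q = 1 − SSW/SST`, computed via sums of squared
deviations (the stratum-size-weighted population variances cancel). `q` lies
in [0, 1], is translation-invariant, and never decreases when a
stratification is refined — all property-tested.

Significance was the one point where the inherited convention had to be
overridden. The commonly cited test transforms `q` to
`F = (N−L)/(L−1) · q/(1−q)` and refers it to a noncentral F with a plug-in
noncentrality built from stratum means. As printed, that noncentrality is
not translation-invariant (with uncentered means and `mean(y) ≠ 0` the
p-value saturates at 1), and even with centered means the plug-in
noncentrality makes the test reject essentially never under the null
(measured 0/2000 in this package's calibration simulation). Since `F` is
algebraically the one-way ANOVA F ratio of the stratification, the central
F(L−1, N−L) reference is exact under the normal null and empirically
calibrated (type-I error ≈ 0.05–0.06 in the same simulation); it is the
default. The centered noncentral variant is retained as `test = "ncf"` for
comparability, and a seeded permutation test is the automatic fallback when
any stratum has fewer than 2 observations.

Interactions overlay two stratifications (Cartesian product of nonempty
combinations) and classify `q_nm` against `q_n`, `q_m`: equal to the sum
(relative tolerance 1e-9) → independent; above the sum → nonlinear enhanced;
above the max → bivariable enhanced; below the min → nonlinear weakened;
otherwise uni-variable weakened. A true product overlay refines both
factors, so `q_nm ≥ max(q_n, q_m)` and the weaken categories cannot arise
there; they are implemented regardless because the classification is defined
on arbitrary q triples (and boundary ties — e.g. a factor overlaid with
itself — fall into the residual band). Continuous drivers default to Jenks
discretisation with L = 5 strata, both exposed, since the field convention
is "natural breaks" with the stratum count rarely stated.

## PLS path modelling

The estimator is the classic iterative composite scheme: standardise
indicators; initialise outer weights at 1; iterate (inner approximation by
the centroid scheme by default — the common software default — with factor
and path schemes switchable; mode-A outer update as indicator–composite
correlations; rescale weights so composites have unit variance) until the
largest outer-weight change falls below 1e-6. Path coefficients are OLS of
each endogenous composite on its parents; loadings are indicator–score
correlations; each block's sign is fixed so its dominant loading is
positive. All blocks are reflective: the quality metrics reported
(loadings, AVE) are the reflective ones. Missing rows are dropped listwise
with the count recorded.

Quality metrics follow the standard definitions: `R²` per endogenous latent
(banded at 0.19 / 0.33 / 0.67), communality = squared loading, AVE = mean
communality per block, `GOF = sqrt(mean communality × mean R²)` (banded at
0.10 / 0.25 / 0.36). Effects decompose over the acyclic path graph: total
effects are the finite geometric series of the path matrix, indirect = total
− direct, additive by construction and cross-checked against explicit path
enumeration. Bootstrap significance resamples observations, refits, aligns
each resample's block signs to the full-sample fit, and reports the normal
p-value on the t-ratio (the plspm-style convention) alongside percentile
p-values and intervals; resampling is fully seeded.

Two modelling decisions deserve emphasis:

- **The recovery world is the composite world.** Mode-A PLS estimates
  relations between *composites*. On data generated from a common-factor
  model its path estimates are attenuated (measured here: maximum absolute
  path error plateauing near 0.05–0.13 for 2–8 indicators per block at
  n = 2000), which no estimator tweak removes — it is the estimand, not a
  bug. The parameter-recovery generator therefore defaults to
  `sim_mode = "composite"`: block noise is constructed orthogonal to the
  weight vector, making each block's composite equal the structural latent,
  so the planted loadings (0.8) and paths are exactly what PLS estimates.
  The `"factor"` mode is kept to demonstrate the attenuation.
- **The shipped default structure** for the pipeline's PLS stage is
  Topography → {Climate, Human}, Climate → Soil, and all four → FVC, with
  FVC a single-indicator latent. It encodes the mechanism the chain is
  built to probe (terrain regulates climate and human pressure; climate
  shapes soil; all act on cover) and is an interpretation — any other
  acyclic structure can be supplied via `pls_model_spec()`.

## The synthetic scenes

`generate_scene()` states one explicit world: elevation high in the
northwest falling southeast (3173–5279 m, the modelled basin's range) with
smoothed random relief; temperature = sea-level value − 0.006 °C/m ×
elevation plus yearly effects (sd 0.5 °C) and cell noise; precipitation
increasing with elevation (0.08 mm/m over a 100 mm base, floored at 0, sd
25 mm); land-use and soil mosaics from quantile-thresholded smooth random
fields; and monthly EVI = baseline (0.45 + land-use class mean ± 0.15 +
smooth field, sd 0.04) + summer-peaked harmonic (amplitude 0.15) + planted
linear trend (default +0.002 /a on the northwest quadrant) + standardised
climate anomalies (coefficients 0.02 / 0.03) + noise (sd 0.02), clipped to
[0, 1]. A 16-day mode doubles each month with independent noise so
maximum-value compositing is exercised. Everything is deterministic under
the seed, with stage-level child seeds derived stably.

Two generator choices matter for interpreting green tests:

- The standardised climate anomalies are made **trend-free per pixel** (the
  OLS linear-in-year component is removed before coupling). Year effects are
  basin-wide, so without this a single climate realisation would tilt every
  pixel's series and the planted τ would no longer be the series' linear
  component — trend "recovery" would be testing the weather draw, not the
  estimator. With it, τ is by construction the only linear term.
- Defaults keep clipping to [0, 1] rare (≪ 0.1 % of observations), so the
  generative model stays effectively linear; worlds with pervasive clipping
  would attenuate planted trends.

What the scenes do *not* emulate: cloud/gap artifacts, sensor noise
structure, spatial autocorrelation of the EVI noise, mixed-pixel effects at
class borders, real phenological shapes, or any radiative-transfer realism.
A green recovery suite therefore establishes that the estimators recover the
stated statistical structure — not that they are robust to MODIS-grade
artifacts.

## Numerical conventions

Empirical quantiles everywhere are type-7 (linear interpolation between
order statistics). Class bins are lower-edge-inclusive with closed top bins.
Degenerate inputs error early and explicitly (constant response in the
geodetector, coincident endmembers, all-masked grids, cyclic path graphs).
Ties in factor ranking break alphabetically and are logged as such. The
pipeline fans one global seed out to per-stage child seeds via a stable
string hash, so stages rerun in isolation reproduce their in-pipeline
results; rerunning a config byte-reproduces every table, and each run
records a config hash, the seed and the package version.

## Known limitations

CSV-dialect raster I/O only; single-CRS workflows; nominal cell areas; no
autocorrelation handling in trend tests; no FDR control across pixels; PLS
supports reflective blocks only (no formative blocks, no higher-order
latents, no covariance-based estimation); the geodetector risk and
ecological detectors are out of scope.
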