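---
title: "Measuring the dimensionality of ecosystem stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the dimensionality of ecosystem stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabdim)
```

## The problem

Ecosystem stability is not one number. The productivity of a grassland can
be *invariable* (it fluctuates little from year to year), *resistant* (a hot
or dry spell barely dents it), and *resilient* (after a dent it returns
quickly to its previous state) — and these three properties need not move
together. When they are tightly coupled, monitoring one of them is enough to
track the others; when they are independent, each must be measured
separately. `stabdim` quantifies all three components from gridded monthly
vegetation-index (NDVI) and climate series and condenses their coupling into
a single statistic, the **dimensionality of stability**.

## The stability components

All series are first linearly detrended and converted to z-score anomalies
per pixel (`zscore_anomalies()`), so secular trends do not contaminate the
variability and sensitivity estimates.

**Temporal invariability** is the inverse coefficient of variation of NDVI:
the long-term mean of the raw series divided by the standard deviation of
its detrended residuals. Using the raw-series mean keeps the numerator
physically interpretable; using detrended residuals in the denominator keeps
a greening trend from counting as instability.

**Resistance and resilience** come from a per-pixel linear autoregressive
model of the monthly NDVI anomaly on the contemporaneous climate anomalies
and its own lag:

$$NDVI_t = \alpha T_t + \beta P_t + \gamma R_t + \delta\, NDVI_{t-1} +
\varepsilon_t$$

with $T$, $P$, $R$ the temperature, precipitation and radiation anomalies.
No intercept is fitted because every regressor is a centred anomaly (a
configuration flag can add one). $|\alpha|, |\beta|, |\gamma|$ measure how
strongly productivity responds to climate perturbation, so raw resistance is
defined as $-(|\alpha| + |\beta| + |\gamma|)/3$: an insensitive pixel scores
0, the maximum. The model specification itself does not dictate how the
three sensitivities combine into one resistance number; the equal-weight
mean of absolute values is the minimal symmetric choice, and
`resistance_score()` also offers `"max"` and `"per_variable"` combiners. A
large $|\delta|$ means the system remembers last month's anomaly, i.e.
returns slowly to its mean state, so raw resilience is $-|\delta|$, again
symmetric in sign. Each component is finally min–max normalized to 0–100
over all retained pixels of one period (`normalize_0_100()`), so that higher
always means more stable; normalization is per period, so values are
comparable across space within a period, and a flag switches to global
normalization if cross-period comparability of absolute levels matters more.

## Dimensionality of stability

Because each pixel contributes a single estimate per component, their
correlations are estimated by space-for-time substitution: pixels are
grouped into county × grassland-type units (`group_space_for_time()`), and
within each unit the three pairwise Pearson correlations are computed across
pixels. These define a 3×3 correlation matrix $C$ with unit diagonal. Its
eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0$ give the semi-axes
$a_i = \lambda_i^{1/2}$ of the ellipsoid spanned by the components, with
volume

$$V = \frac{\pi^{n/2}}{\Gamma(n/2 + 1)} \prod_{i=1}^{n} \lambda_i^{1/2}.$$

Semi-axes are normalized by the largest, and the normalized volume is
divided by its theoretical maximum (the unit sphere), giving

$$D = \prod_i \left(\lambda_i / \lambda_{\max}\right)^{1/2} \in [0, 1].$$

$D = 1$ means the components are uncorrelated (a sphere — every stability
dimension carries independent information); $D = 0$ means they are fully
collinear (a "cigar" — one dimension suffices). Two design points deserve
note. First, the components are separately normalized, so their covariance
structure coincides with their correlation structure up to scale; working
with the unit-diagonal correlation matrix makes the sphere bound exact.
Second, the semi-axis convention $a_i = \lambda_i^{1/2}$ is the one
consistent with the volume formula and with ellipsoid geometry (the
alternative $a_i = \lambda_i$ would square the volume's dependence on the
eigenvalues); `ellipsoid_dimensionality()` implements the square-root
convention throughout. Correlation p-values are reported but by default do
not zero out non-significant correlations; `sig_level` enables that
filtering where a sparser matrix is wanted.

Between two periods, `delta_dimensionality()` reports per-unit
$\Delta D = D_2 - D_1$ and pixel-weighted (optionally unweighted) summaries:
the mean change, the share of area decreasing, and — among decreasing units
— the share whose relative decrease exceeds 20 %.

## Grazing pressure and attribution

Livestock yearbooks record head counts per county; `to_sheep_units()`
converts them at the conventional rates (sheep/goat = 1 standard sheep unit,
yak/donkey/horse = 4), and `grazing_intensity()` divides by the county's
natural-grassland area (SHU ha⁻¹). Because the records carry no breakdown by
grassland type, every type within a county inherits the county's GI. Per
period, OLS trends of mean annual temperature, annual precipitation, annual
radiation and GI are computed per unit; their between-period changes are the
predictors, and $\Delta D$ the response, of the attribution stage: simple
bivariate regressions (`bivariate_relationships()`) plus a regression random
forest (`random_forest_attribution()`, 500 trees, `mtry = 2`, i.e. about a
third of four predictors). Variable importance is %IncMSE — the increase in
out-of-bag MSE when one predictor is permuted. Implementations differ on the
scaling of this statistic, so both variants are exposed: the default
`"pct_baseline"` expresses the raw mean OOB-MSE increase as a percentage of
the baseline OOB MSE (directly interpretable as "permuting this predictor
costs x % accuracy"), and `"scaled"` divides the mean increase by its
standard error, the convention of the underlying `randomForest` package.
Model fit is the out-of-bag $R^2$.

## The synthetic-data generator

No public archive accompanies the analysis this package operationalizes, so
the generator produces all inputs with known ground truth, at a reduced
spatial scale. It emulates:

- a county × grassland-type mosaic (`make_landscape()`), with log-normal
  county areas and an optional group dropout that mimics counties lacking
  some grassland types;
- monthly climate (`simulate_climate()`) as seasonal harmonic + linear trend
  + white noise per pixel, with defaults chosen once to resemble a
  high-altitude continental grassland: temperature mean 0 °C with 12 °C
  seasonal amplitude, precipitation mean 40 mm mo⁻¹ with 35 mm amplitude
  (clipped at 0), radiation mean 600 MJ m⁻² mo⁻¹ with 200 amplitude;
- NDVI (`simulate_ndvi()`) by running the fitting equation generatively:
  z-score the climate, iterate the anomaly recursion with per-pixel
  $(\alpha, \beta, \gamma, \delta)$ and innovation SD, then map anomalies
  back through a seasonal mean profile (mean 0.45, amplitude 0.15, anomaly
  scale 0.08 NDVI per standardized unit) and clip to [0, 1]. Adopting the
  fitting equation as the generator is deliberate: it makes parameter
  recovery a well-posed, exactly checkable contract;
- per-pixel coefficients drawn from a one-factor model
  (`make_ground_truth()`): a shared pixel-level latent factor with loading
  $\ell$ enters every coefficient and the log innovation SD, so the derived
  stability components are correlated across pixels to a controllable
  degree. $\ell = 0$ is the high-dimensionality preset (independent draws),
  $\ell = 0.8$ the low-dimensionality preset; on the same landscape and
  seeds the latter must — and in tests does — yield strictly smaller mean
  $D$;
- county livestock series (`simulate_livestock()`) following a declared SHU
  density with per-period trends, split among five species at fixed shares
  and rounded to integer heads;
- two periods (2000–2008 and 2009–2017 by default) generated by
  concatenation with independently configurable climate and livestock trends
  per period. Detrending, z-scoring, fitting and normalization are all
  performed per period, since every stability quantity is defined within a
  period.

What the generator does **not** emulate: spatial autocorrelation beyond the
county/type structure, cloud/gap artifacts beyond optional white-noise
spikes, mixed pixels, or the seasonally varying *variance* of real NDVI. A
passing suite therefore demonstrates correctness of the estimators under the
stated generative model, not robustness to every pathology of real imagery.

### Coefficient scales and exact recovery

The generator's anomaly recursion is defined on z-scored climate and the
emitted NDVI anomaly. When the pipeline additionally z-scores the NDVI
anomaly (the default, `ndvi_scale = "zscore"`, matching the convention that
*all* variables are standardized), the fitted $\alpha, \beta, \gamma$ are
the generating ones divided by the pixel's anomaly SD, while $\delta$ is
recovered unchanged — scale-free, like every correlation and every
normalized map derived from it. Exact numerical recovery of all four
generating coefficients is therefore defined on the emitted-anomaly scale
(`ndvi_scale = "detrend"`, or fitting directly on the generator's anomaly
output): there a noiseless simulation refits to machine precision, and 500
pixels × 216 months at innovation SD 0.1 recover the coefficients with
median absolute error well under 0.05.

### A note on anomaly seasonality

Anomalies here are single-mean z-scores, so the seasonal cycle remains in
both NDVI and climate anomalies. The autoregressive fit then partly reflects
the shared seasonality, which inflates the structural correlation among the
derived components; synthetic dimensionalities are consequently much lower
than those typical of deseasonalized real-data analyses. This does not
affect the contracts the tests check — coefficient recovery on the
generating scale, rank recovery of $|\delta|$, and the strict preset
ordering of $D$ — but absolute synthetic $D$ values should not be read as
field-realistic. Removing a monthly climatology before z-scoring would be
the natural extension for real data.

## Numerical choices and degenerate inputs

- Eigenvalues of a correlation matrix in $[-10^{-10}, 0)$ are clipped to 0
  with a message; anything more negative is rejected as an invalid matrix.
  Asymmetry and non-unit diagonals beyond $10^{-10}$ are also rejected.
- A pixel whose detrended NDVI SD is at rounding-noise level (below
  $10^{-10}$ relative) has undefined invariability and is returned as `NA`,
  never as infinity; `NA` pixels are excluded from unit datasets before
  correlation.
- Zero-variance pixels make z-scoring impossible and raise an error naming
  the pixel; collinear autoregressive designs (condition number above
  $10^8$) are flagged and propagate `NA` through the stability scores.
- Min–max normalization with all values identical is an error rather than a
  silent constant.
- The low-NDVI filter (threshold 0.1, the conventional cutoff for sparse
  vegetation) uses calendar-year means over complete years and excludes a
  pixel that fails in *any* year — the conservative reading — and the mask
  is applied to every co-registered variable and across both periods, so
  units are built from a common pixel set.
- Savitzky–Golay smoothing defaults to window 5, polynomial order 2, applied
  to NDVI only — common practice for monthly satellite vegetation indices.
- A spatial dataset needs at least `min_pixels = 30` valid pixels (a
  conventional floor for a stable Pearson correlation); the group sizes of
  the original study are not public, so this is configurable.
- All randomness flows from a single root seed split deterministically per
  stage; identical configurations yield bit-identical outputs.

## Problem sizes used in the validation suite

The test suite runs entirely on synthetic data sized for interactive use:
landscapes of 2–6 counties × 2–3 types with 8–60 pixels per group, 9-year
(108-month) periods for pipeline-level checks, 216-month single periods with
500 pixels for coefficient recovery, attribution tables of 200 units over
10 seeds, and the 122-county dropout scenario for the grouping logic. These
sizes were chosen as the smallest at which the statistical contracts are
comfortably non-marginal.

## Worked example

```{r, eval = FALSE}
library(stabdim)
cfg <- pipeline_config(n_counties = 3, types_per_county = 2,
                       pixels_per_group = 60, min_pixels = 30, seed = 1)
res <- run_pipeline(cfg)
res
res$dimensionality[[1]][, c("unit_id", "n_pixels", "r_inv_rst",
                            "dimensionality")]
```

## Limitations

- The space-for-time design equates across-pixel with over-time covariation;
  where that substitution fails (strong within-unit environmental
  gradients), the correlation matrix mixes spatial and temporal signals.
- County-level grazing intensity cannot resolve within-county contrasts
  between grassland types.
- The autoregressive model is linear and memoryless beyond lag 1; slow,
  nonlinear or lagged-beyond-one-month vegetation responses are absorbed
  into the residual.
- With three components the dimensionality statistic compresses three
  correlations into one number; inspect the pairwise correlations alongside
  $D$ before interpreting changes.
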