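---
title: "Methods: peatland monitoring with composites, RSEI and robust trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peatland monitoring with composites, RSEI and robust trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatwatch)
```

## Purpose and scope

`peatwatch` implements a complete analysis chain for multi-decadal monitoring
of raised-bog landscapes from annual multispectral composites: QA masking and
product scaling, seasonal scene selection, medoid compositing, two-stage
Random-Forest land-cover classification with temporal filtering and Markov
transition accounting, a per-year PCA-based Remote Sensing Ecological Index
(RSEI), robust monotonic-trend statistics with autocorrelation handling,
hydroclimate aggregation and anomaly correlation, and delta-RSEI change
mapping with patch statistics. Because multi-decadal satellite archives
cannot be shipped with a package, every stage is exercised against a
synthetic raised-bog landscape generator with known ground truth; the test
suite is the specification of what each stage guarantees.

## The synthetic world

The generator (`sim_config()`, `simulate_climate()`, `simulate_landscape()`,
`inject_clouds()`) emulates the statistical structure the analysis assumes,
not the radiometry of any particular sensor:

* **Landscape.** Three classes - forest (1), bog (2), grassland (3) - on a
  30 m grid. Year 1 has a contiguous central bog (raised bogs are single
  domes, not scattered pixels), grassland patches grown from a few seed
  points, and a forest matrix. Default initial shares are 52.4 / 37.2 /
  10.4 %, a forest-dominated mosaic with a large open bog.
* **Succession.** Each year, every bog pixel 8-adjacent to forest converts
  to forest with probability
  `p = clamp(base_rate * (1 + deficit_sensitivity * z), 0, 1)`, where `z`
  is the standardized *negative* annual climatic water balance - drier years
  push the forest edge faster. This edge-restricted process is the simplest
  one that reproduces dominant bog-to-forest transitions with spatially
  coherent change patches; it is a stand-in for the real mechanism, not an
  estimate of any site's true rate. Defaults: `base_rate = 0.05` per year
  per eligible pixel, `deficit_sensitivity = 0.5`. Grassland-to-forest
  conversion is available but disabled by default.
* **Spectra.** Per-pixel reflectance is the class mean plus iid Gaussian
  noise (`sd = 0.01`). Class means are ecologically ordered: forest dark in
  the visible with moderate NIR, open bog brightest in SWIR (dry moss and
  exposed peat), grassland highest in NIR. The thermal band is the class
  mean plus a scaled summer temperature anomaly plus noise; the *bog* class
  is the warm class (298.5 K against 294 K forest and 296 K grassland)
  because in the system being emulated surface heat opposes ecological
  condition - dry degraded peat surfaces run hottest in summer. With the
  heat axis oriented this way, the four RSEI components carry a consistent
  condition gradient, which is what makes the orientation contract (below)
  testable.
* **Climate.** Each monthly variable (ppt, pet, cwd, aet, runoff, tmean) is
  an independent July-peaking cosine cycle plus linear trend plus Gaussian
  noise, floored at zero for fluxes; `cwb = ppt - pet` holds exactly by
  construction. Defaults loosely emulate a maritime Baltic lowland
  (~700 mm yr⁻¹ precipitation, warming ~0.035 K yr⁻¹, mild drying).
* **Clouds.** Random circular disks are accumulated until exactly
  `round(fraction * n_pixels)` pixels are flagged (cloud bit set, bright
  constant reflectance). Disk radii up to one sixth of the grid make the
  masking spatially clumpy, as real cloud fields are.

What the generator does **not** emulate: mixed pixels and diffuse ecotones,
sensor change and calibration drift, phenology within the season,
topography, peat hydrology. A green end-to-end test therefore establishes
that the *algorithms* recover a known process from clean, separable data -
it says nothing about classification accuracy on real imagery, where class
overlap, not algorithmic error, dominates.

All randomness flows from one master seed through `derive_seed(seed, salt)`
sub-streams, so identical seeds give bit-identical outputs while stages stay
statistically independent.

## Preprocessing

QA words are decoded bitwise (fill, cirrus, cloud, cloud shadow, snow/ice;
Collection-2-style bit layout by default); saturation drops the whole pixel
vector to keep composite spectra internally consistent. Reflectance scaling
uses the standard Collection 2 Level-2 constants (`DN * 2.75e-5 - 0.2`),
temperature `DN * 0.00341802 + 149 K`; out-of-range reflectance is flagged
invalid, never clipped.

Seasonal selection prefers June acquisitions; if fewer than 80 % of pixels
(configurable - the trigger fraction is a free parameter of the analysis)
have at least one valid June observation, the window extends to
June-August, and a year with no valid observation anywhere is flagged
missing rather than fabricated.

The medoid composite takes, per pixel, the per-band median over valid
observations of the six reflectance bands and then copies the *single
observation* closest (Euclidean distance over the six bands; thermal carried
along) to that median vector. Composite spectra are therefore always
observed spectra, never per-band mixtures - the property the test suite
checks against an exhaustive per-pixel oracle. Distance ties break to the
earliest acquisition for determinism.

## Indicators

NDVI, NDMI, NBR and MNDWI are plain normalized differences with zero
denominators mapped to nodata. Tasseled Cap wetness uses published
reflectance-based coefficient sets per sensor (TM set for TM/ETM+ and the
synthetic sensor, OLI set for OLI), shipped as a versioned CSV.

NDBSI = (SI + IBI)/2 ships in two variants. The default `table_verbatim`
follows the printed source formula, whose SI algebraically collapses to a
red-blue contrast with no SWIR term; `standard_si` is the conventional
bare-soil index over swir1/red vs nir/blue. The verbatim form is the default
for fidelity; the standard form is provided because the printed SI is most
plausibly a typographical collapse. Neither is presented as the original
author's intent, and the variant used is recorded per run.

Land surface temperature defaults to the Level-2 product pathway (scaled
Kelvin, plausibility-screened to -20...60 °C). A single-channel
emissivity-corrected formula (`T / (1 + (lambda T / rho) ln e) - 273.15`)
and the brightness-temperature inversion `K2 / ln(K1/L + 1)` are provided
for completeness; the brightness-temperature formula is implemented against
thermal radiance (the printed source references a SWIR band where a thermal
band is physically required).

## Classification

Training is two-stage: a maximum-likelihood seed classification of
reference-year composites (first year plus every fifth year, eight in a
41-year record) from per-class Gaussian statistics, then *stable pixels* -
classified identically in every reference year - are sampled, balanced per
class, with predictors (6 bands + NDVI, NDMI, NBR, MNDWI) extracted at every
reference year and pooled. A 75/25 uniform random split feeds a Random
Forest (in-package Rcpp implementation: bootstrap aggregation, Gini splits,
`floor(sqrt(p))` features per node, 200 trees by default, deterministic
given a seed; no RF package exists in the target environment). Accuracy is
assessed on a stratified validation subset (up to 1 500 rows per class; all
rows with a message when fewer exist), reporting overall accuracy, Cohen's
kappa, and per-class UA/PA, Type I = 1 - UA, Type II = 1 - PA and
F1 = 2·UA·PA/(UA+PA).

Annual maps pass a 5-year moving-window pixel-wise majority filter,
truncated at the series ends; on a tie the centre-year label is retained
when it participates, otherwise the lowest tied class code wins (both rules
are determinism choices the source leaves open). Class areas are pixel
counts times pixel area. The Markov transition matrix defaults to
*start-to-end* frequencies (fraction of first-year class-i pixels classified
j in the final year) because published whole-period persistence values are
consistent with endpoint accounting rather than annual steps;
`pooled_annual` pooling over consecutive-year pairs is available.

## RSEI

For each year the four components (NDVI, wetness, NDBSI, LST) are min-max
normalized over that year's valid pixels (no percentile clipping - the
source states only "normalized"), centred, and decomposed by covariance PCA
(components already share the [0, 1] scale after normalization, so
correlation PCA would only reweight noise). PC1 scores are oriented by the
sign of the NDVI loading - the "1 - PC1" convention with the eigenvector
sign ambiguity resolved so that the index correlates positively with
greenness and wetness and negatively with dryness and heat - then min-max
rescaled to [0, 1]. The orientation decision, loadings and variance share
are recorded per year. Categories are the five 0.2-wide levels with
left-closed boundaries (0.2 belongs to level 2) and a closed last bin,
implemented with `findInterval` so boundary values are not lost to
floating-point division.

Per-year PCA means loadings can drift between years; this is a known
limitation of the index family (class-stratified summaries, which the
pipeline always produces when classification is enabled, are the mitigation,
not a fix).

## Trend statistics

The Theil-Sen slope is the median of all pairwise slopes, with the 95 %
interval from the rank-order method on the sorted slopes using the
tie-adjusted Mann-Kendall variance. Mann-Kendall uses the normal
approximation with continuity correction and tie adjustment; an all-equal
series returns tau 0, p 1.

Serial correlation is handled adaptively: lag-1 autocorrelation of
OLS-detrended residuals is tested against `1.96/sqrt(n)`; when significant,
`trend_test()` switches to trend-free prewhitening. The TFPW variant here is
the *iterative, trend-preserving* form: the Sen slope and the lag-1
coefficient of the detrended series are estimated jointly by iteration (with
the small-sample bias correction `(n r + 2)/(n - 4)`, chosen so that the
estimator is centred on the true coefficient - verified in simulation
against known AR(1) inputs), and the test is applied to
`w_t = (y_t - r1 y_{t-1})/(1 - r1)`, which removes the AR(1) component while
preserving a linear trend exactly. The widely used blended recipe (re-adding
the estimated trend to prewhitened residuals) was implemented first and
rejected: under pure AR(1) noise it re-injects the spurious Sen slope onto
variance-reduced noise and its empirical false-positive rate stays far above
nominal, which defeats the purpose of the correction. Residual imperfection
of the whitening is acknowledged by a Hamed-Rao-style variance scaling in
the final test, and the reported confidence interval is widened by the lag-1
variance-inflation factor `(1 + r1)/(1 - r1)`. The suite verifies the
empirical type-I error of the raw test on iid noise and of TFPW under
AR(1) with coefficient 0.6, and Sen-interval coverage under trend plus
noise.

Climate series aggregate to June-August or annual summaries (sums for
fluxes, means for states), anomalies are deviations from the full-record
baseline by default (the source does not state its baseline), and
class-RSEI / climate-anomaly associations are plain Pearson correlations on
raw (not detrended) aligned series - detrending is left to the caller, as
the source does not state which was used.

## Change mapping

Delta-RSEI is the last-minus-first-year difference on the common valid mask.
The "changed" threshold is a free parameter exposed as two rules - absolute
value (default 0.02) or a multiple of the delta standard deviation (default
0.5) - with the resolved value logged per run; the published threshold
behind any particular changed-area figure is not recoverable. Summaries use
linear-interpolation percentiles; improved plus degraded hectares equal the
changed hectares exactly because a strictly positive threshold excludes
zero-delta pixels. Patches are connected components of equal-sign changed
pixels, 8-connectivity by default (diagonal woody spread is physically
plausible), labelled by an Rcpp flood fill and checked in the suite against
an independent BFS oracle.

## Numerical and degenerate-input choices

* Constant component layers abort normalization with the component named;
  zero-variance PC1 scores abort RSEI.
* Singular class covariances in the maximum-likelihood stage are
  ridge-regularised with a warning; exact likelihood ties go to the lowest
  class code everywhere (ML, RF votes, majority filter).
* Reflectance outside [0, 1] and LST outside -20...60 °C are flagged, not
  clipped.
* Rasters are in-memory matrices with grid metadata; on-disk interchange is
  the Esri ASCII grid written at `%.17g`, so round trips are bit-exact. (No
  GeoTIFF driver exists in the target environment; the format choice is an
  infrastructure substitution, not a method choice.)
* Configs serialize to JSON; a run's resolved configuration and a log of
  every resolved free parameter are written next to the outputs.

## End-to-end guarantees and their limits

On the default 150 x 150, 41-year synthetic world the suite requires
overall accuracy >= 0.95 and kappa >= 0.9, the orientation contract for every
year, row-stochastic transition matrices, exact change-area partitioning,
and recovery of the realized bog-to-forest conversion fraction by the
start-to-end transition estimate within its binomial confidence interval.
That last comparison is made *on the jointly observed support* (pixels
classified in both endpoint years): cloud masking is spatially clumpy while
conversion concentrates at the bog edge, so the observed subsample's
realized fraction is the estimable parameter - an estimator cannot be asked
to recover conversions under clouds it never saw. With separable spectra
the classifier is essentially perfect, so this check currently constrains
the accounting pipeline (compositing, masking, map algebra) rather than the
classifier itself; the classifier's own quality is checked separately on
held-out samples and on Gaussian-overlap fixtures.
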