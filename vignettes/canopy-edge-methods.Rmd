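---
title: "Methods: canopy height change, edge effects and the synthetic landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy height change, edge effects and the synthetic landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyedge)
```

## The scientific problem

Logged tropical forests regrow, but the regrowth is shaped by where a forest
patch sits: how close it is to an oil-palm plantation edge, and whether it
occupies a ridge or a valley. Repeat airborne LiDAR surveys measure
top-of-canopy height (TCH) at 30 m resolution across whole landscapes, so
the change between two surveys (ΔTCH, in metres; positive = growth) can be
modelled against landscape covariates. `canopyedge` implements that analysis
end to end for a survey pair spanning a hot ENSO drought: terrain metrics,
the repeat-survey filtering ledger, field-plot canopy statistics,
micrometeorological formulas, and — the inference core — an asymptotic
edge-effect regression with spatial autocorrelation and subset-ensemble
uncertainty.

## The model

The height change of pixel *i* is modelled as

$$\Delta TCH_i \;=\; \beta_0 + \beta_1\,TPI_i + \beta_2\,TCH_{2014,i}
\;-\; b\,e^{-c\,D_i} \;+\; \varepsilon_i ,$$

where $TPI$ is the topographic position index (positive on ridges, negative
in valleys), $TCH_{2014}$ the initial canopy height, and $D$ the distance to
the nearest oil-palm edge. The exponential term is an edge *penalty* of
amplitude $b$ (m) decaying at rate $c$ (per m): growth saturates at the
plateau $\beta_0 + \beta_1 TPI + \beta_2 TCH$ far from the edge and is
depressed by up to $b$ at the edge itself. The distance at which net change
crosses zero is available in closed form
(`edge_penetration_distance()`): $D_0 = -\ln(A/b)/c$ with
$A = \beta_0+\beta_1 TPI+\beta_2 TCH$, defined when $0 < A < b$.

Candidate models (`build_candidates()`) comprise purely linear predictors,
a linear distance term, the asymptotic form, and the asymptotic form with
TCH×TPI and TCH×D interactions; they are compared by AIC
($2k - 2\ln L$, Gaussian likelihood, $k$ counting the residual variance and,
for spatial fits, the correlogram range).

### Fitting

`fit_nls()` minimizes the residual sum of squares by damped Gauss–Newton
with an analytic Jacobian. The decay rate is optimized as $\log c$ so it
stays positive; starts are taken from a grid of rates
$c_0 \in \{0.001, 0.005, 0.02\}$, with the remaining coefficients started at
their profiled linear least-squares solution given $c_0$; the best converged
start by residual sum of squares wins. Accepted steps never increase the
objective (the step path is retained and asserted in the tests). Linear
candidates are solved exactly by ordinary least squares.

`fit_gls_spatial()` adds residual correlation
$\mathrm{corr}(\varepsilon_i,\varepsilon_j) = e^{-d_{ij}/\rho}$ and
estimates everything by maximum likelihood: the residual variance is
profiled out, the mean-function coefficients are obtained by Gauss–Newton on
Cholesky-whitened data for a given $\rho$, and $\rho$ itself by
golden-section search of the profiled log-likelihood over
$[1, 1000]$ m on the log scale. There is no nugget by default (a `nugget`
fraction is available behind a flag). The covariance algebra is dense, so
the function enforces an upper problem size (6000 rows); within the
package's workflow the spatial fit is used on subsets. Cholesky failures are
retried with a jittered diagonal before erroring. In tests the
implementation is cross-checked against an independent nonlinear GLS oracle
(`nlme::gnls` with an exponential spatial correlation structure) and agrees
in coefficients, range and log-likelihood.

### Subset ensemble and corrected intervals

Dense spatial fits on the full pixel set are impractical, so stability is
measured on random subsets: `subset_ensemble()` fits the model to 24 random
subsets of 3000, 4000 and 5000 pixels and reports per-parameter means,
medians and coefficients of variation (CV% = 100·sd/|mean|). Within one
repetition the three sizes are *nested* (the first 3000 of a permuted index
vector, then 4000, then 5000); repetitions are independent. Nesting is a
common-random-number device: it removes between-repetition noise from the
size comparison, sharpening the check that CV% shrinks with subset size,
without changing any marginal distribution. Confidence intervals estimated
on an *n*-pixel subset are rescaled to the full *N*-pixel dataset as
$CI_{corrected} = CI_{model}\sqrt{n/N}$ (`corrected_intervals()`;
$\sqrt{5000/36655} = 0.3693$).

Prediction curves (`prediction_curves()`) evaluate the fitted model for
short, medium and tall canopies (5, 20, 35 m) on valleys and hilltops (TPI
−8.2 and 9.0, the 5th and 95th landscape quantiles) against distance, with a
delta-method band from the across-repetition parameter covariance, scaled by
$\sqrt{n/N}$.

## Terrain metrics

* **TPI** (`compute_tpi()`): the DTM is averaged to 10 m; each cell's
  elevation is compared with the mean over a circular 1 ha neighbourhood
  (radius 56.42 m, focal cell excluded); the result is smoothed by the same
  1 ha disc mean and block-averaged to 30 m. The disc geometry is a design
  choice (the neighbourhood's exact shape is configurable via `radius_m`);
  neighbourhoods are truncated at raster borders. The implementation is
  asserted equal (to 1e-9) to a brute-force per-cell oracle.
* **TWI** (`compute_twi()`): the DTM is averaged to 30 m, sinks are filled
  (Planchon–Darboux with a small epsilon gradient), flow is routed by
  steepest descent among the 8 neighbours, and
  $TWI = \ln(a/\tan\beta)$ with the specific catchment area
  $a$ = accumulated cells × cell area / cell width and slope from central
  differences floored at $\tan\beta \ge 10^{-4}$ to keep flats finite.
  Single-direction (D8) routing is deliberate; dispersive routing is out of
  scope.
* **Distance to edge** (`distance_to_edge()`): an exact Euclidean distance
  transform between cell centres, with oil-palm cells at distance zero. A
  centre-to-centre raster distance differs from a polygon-boundary distance
  by at most half a cell diagonal (≈ 21 m at 30 m resolution).

## Repeat-survey gridding and the filtering ledger

Synthetic labelled returns can be gridded from scratch: ground returns are
triangulated (Bowyer–Watson) and linearly interpolated to a 1 m DTM;
canopy returns form a 2 m canopy height model by per-cell maxima of height
above ground (clamped at zero); TCH is the 15×15 block mean, valid only when
at least half the sub-cells are valid. The pit-free CHM refinement used on
real point clouds is not reproduced — the generator's returns are dense and
artefact-free, which is precisely what that refinement corrects for.

`apply_filter_ledger()` recomputes every exclusion flag from scratch in a
fixed order: non-forest cover; a 200 m buffer around clear-cuts; road cells
plus a 30 m buffer; first-survey point density below 10 pts/m²; and finally
trimming of the lower and upper 1% of ΔTCH among the surviving rows. The
trim is rank-based (`floor(f·n)` rows per tail), applied after the density
filter — whether the original analysis trimmed before or after that filter
is not recoverable, and the assumption is documented here. Because flags are
recomputed rather than accumulated, the ledger is idempotent, and the audit
(rows removed / remaining per rule) reconstructs every decision.

## Field-plot statistics

* DBH measurement error: $s = 0.9036 + 0.006214\,DBH$ (cm).
* Growth QC (`clean_growth()`): stems growing ≥ 5 cm/yr or shrinking by
  ≥ 12·s are assigned the mean increment of unflagged stems of the same
  per-plot DBH quartile, falling back to the plot and then the network mean.
  The 12·s shrinkage multiplier is implemented as printed in the source
  protocol and is configurable; size classes as per-plot quartiles are a
  design choice (the protocol says only "same size, same plot").
* Allometry (`fit_allometry()`): log–log power laws for height and crown
  area with Duan's smearing factor on back-transformation.
* Crown-area-weighted TCH (`crown_weighted_tch()`): stems ranked by crown
  area (ties by DBH, then id), selected until cumulative crown area first
  reaches the 625 m² plot area (the crossing stem included whole), then a
  crown-area-weighted mean height. Invariant to input order and to common
  rescaling of areas and threshold.
* Basal-area dynamics: mortality as the initial basal area of dying stems,
  growth as the increment of survivors; recruits are reported separately and
  excluded from both terms (a documented convention).
* PAI from canopy openness: Beer–Lambert inversion
  $PAI = -\ln(\text{openness})/k$, default $k = 0.5$. The published openness
  processing chain upstream of this step is out of scope; the inversion is a
  deliberate simple stand-in and its $k$ is configurable.

## Microclimate

Saturation vapour pressure follows Bolton,
$e_s = 6.112\,e^{17.67\,T/(T+243.5)}$ hPa, and
$VPD = (100-RH)/100 \cdot e_s$. Monthly means average per-record VPD (not
VPD of the means — the formula is convex in its inputs, and the Jensen gap
is asserted in the tests). Running precipitation uses a *trailing* 30-day
window (undefined for the first 29 days; calendar gaps invalidate windows
unless a tolerance is raised). ENSO anomalies compare an event month against
the mean over all months of the baseline years (2013–2014 by default;
a month-matched baseline can be obtained by filtering the monthly table).

## The synthetic landscape generator

The generator is first-class, tested code: every downstream stage runs on
scenes whose statistical structure is controlled and whose generating truth
is stored.

* **Terrain**: two kernel-smoothed Gaussian fields — a broad component
  (600 m correlation, 120 m sd) for regional hills over lowlands plus a
  fine-scale component (40 m, 33 m sd) — on a gentle linear trend. The
  fine-scale amplitude was calibrated once so the generated TPI distribution
  reproduces the study landscape's quantiles (5th/95th ≈ −8/+9, extremes
  ≈ −20/+20 against the reported −24/+35).
* **Cover**: cells below the 0.4 elevation quantile become oil palm (the
  study mosaic was ≈ 40% plantation, concentrated in the lowlands);
  circular clear-cut patches and straight 30 m roads are stamped into the
  forest. The geometry is deliberately simple — just enough structure to
  exercise every filter.
* **Canopy**: initial height is a monotone transform (probit rank map) of a
  smooth logging-intensity field spanning 0–64 m over a 300 m correlation
  length (logging intensity in such mosaics varies over small scales).
  ΔTCH is the generating model's deterministic surface plus Gaussian noise
  of sd 0.9 m split equally between a spatially correlated component
  (exponential correlogram, range 90 m, simulated by circulant embedding)
  and an uncorrelated nugget. The residual sd and range are free knobs of
  the emulation — the source analysis does not report them — and 0.9 m keeps
  interior pixel changes physically plausible.
* **Point density**: lognormal with mean and sd 13.2 pts/m² (the first
  survey's sensor), with an additive negative height bias of 0.2 m per
  point of shortfall below 10 pts/m², so roughly half the pixels fall below
  the density threshold, as in the study.
* **Plots and climate**: five censuses with power-law allometries, Gaussian
  growth, Bernoulli mortality and Poisson recruitment; an aseasonal daily
  climate with additive event-window anomalies (+2.1 °C and −11.2% RH,
  which together imply a +140% VPD anomaly through Bolton's formula; the
  temperature sd of 0.25 °C represents a plot-network mean series).

All randomness flows from the single `scene_config()` seed through named
sub-streams, so identical configurations yield bitwise-identical scenes and
stages can be regenerated independently.

### What the generator does and does not emulate

It reproduces the *statistical* structure the inference relies on: covariate
distributions matching the published ranges, the generating model with
spatially correlated residuals, density-dependent height bias, and cover
geometry exercising every exclusion rule. It does not emulate sensor
waveforms, flight-line artefacts, co-registration error, species
composition, or wind-driven disturbance. Passing the recovery suite
therefore demonstrates that the estimation machinery is unbiased and
correctly calibrated under the assumed error structure — not that the
published real-data coefficients are correct.

## Problem sizes and numerical choices

The recovery experiment mirrors the published analysis sizes: 36,655
analysis pixels, 24 repetitions, subsets of 3000/4000/5000. The default
scene is 28.8 × 28.8 km so that the 36,655 pixels are a scattered subset of
the forest pool — the study's retained pixels are likewise a scattered
minority of a much larger surveyed mosaic, and with 90 m-correlated noise a
compact scene would leave too few independent noise patches for the
generating coefficients to be recoverable by any estimator. Spatial GLS
examples and tests run at a few hundred pixels, where the dense covariance
algebra is exact and fast; the ensemble's default fitting method is
nonlinear least squares.

Other numerical choices: nearest-rank trimming with `floor(f·n)` per tail;
the 50% valid-sub-cell rule for 30 m TCH validity; buffer distances as
centre-to-centre Euclidean; multi-start tie-break by lowest residual sum of
squares; golden-section tolerance of 0.02 on $\log\rho$; slope floor
$10^{-4}$ in TWI; circulant-embedding eigenvalue clamping at zero (the
embedding of an exponential covariance can be marginally indefinite; the
clamped mass is negligible at the padding used).

## Known limitations

* The spatial GLS is dense ($O(n^3)$); no sparse or low-rank approximation
  is provided.
* The raster IO is the plain-text ESRI ASCII grid; GeoTIFF is not supported.
* D8 flow routing underestimates catchment dispersion on convex hillslopes.
* The ground-point triangulation is quadratic in point count and intended
  for synthetic scenes, not full survey point clouds.
* The zero-crossing distance of the fitted model at typical covariates
  (≈ 54 m at TPI 0, TCH 0; ≈ 82 m at TCH 5) brackets, but does not exactly
  reproduce, the "about 70 m" quoted for the real landscape — the covariate
  values behind that statement are not recoverable, so the package asserts
  only the closed form and its hand-derived values.
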