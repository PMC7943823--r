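# canopyedge

Edge effects on canopy height change in fragmented, logged tropical forest.

Repeat airborne LiDAR surveys measure top-of-canopy height (TCH) at 30 m
resolution across whole landscapes. Over a survey pair spanning the hot,
dry 2015–16 ENSO event, the height *change* ΔTCH of regenerating logged
forest in an oil-palm mosaic depends on where a pixel sits: its distance to
the plantation edge, its topographic position, and how tall the canopy
already was. `canopyedge` is for forest ecologists and remote-sensing
analysts who want to fit and probe that model — and to test the whole
pipeline on synthetic landscapes with known generating truth, so no data
download is required.

## The model

For pixel *i*,

```
ΔTCH_i = β0 + β1·TPI_i + β2·TCH_2014,i − b·exp(−c·D_i) + ε_i
```

where TPI is the topographic position index (ridges positive, valleys
negative), TCH_2014 the initial canopy height, D the distance to the
nearest oil-palm edge, and ε Gaussian residual error, optionally with an
exponential spatial correlogram `corr(ε_i, ε_j) = exp(−d_ij/ρ)`. The
exponential term is an edge penalty: growth saturates at the plateau
`β0 + β1·TPI + β2·TCH` in the forest interior and is depressed by up to
`b` metres at the edge. Fitting is by damped Gauss–Newton nonlinear least
squares (`fit_nls()`) or by profile-ML spatial GLS (`fit_gls_spatial()`),
candidates are compared by AIC, and uncertainty comes from a 24-repetition
random-subset ensemble with sample-size-corrected confidence intervals
(`CI_corrected = CI_model·√(n/N)`).

The package also provides the surrounding pipeline: terrain metrics (TPI,
topographic wetness index, Euclidean distance to edge), the repeat-survey
filtering ledger (non-forest cover, clear-cut and road buffers, point
density, 1% trim — with a full audit), field-plot canopy statistics (DBH
quality control, allometry with smearing correction, crown-area-weighted
plot height, basal-area mortality/growth), micrometeorology (Bolton
saturation vapour pressure, VPD, running precipitation, ENSO anomalies),
and a seeded synthetic-landscape generator.

## Worked example

Simulate a 6 × 6 km landscape, draw 8000 forest pixels, and fit the
asymptotic edge-effect model:

```r
library(canopyedge)

cfg <- scene_config(seed = 1, extent_m = c(6000, 6000))
tab <- simulate_pixel_table(cfg, n_pixels = 8000)
fit <- fit_nls(build_candidates()$asymptotic, tab)
fit
#> <edge_model_fit> asymptotic (nls), n = 8000
#>    beta0 beta_tpi beta_tch        b        c
#>  0.64172 -0.01862 -0.01723  0.84438  0.00489
#>   sigma = 0.8875, logLik = -10394.0, AIC = 20800.0
```

The scene was generated with β0 = 0.6576, β1 = −0.02142, β2 = −0.0172,
b = 0.8553, c = 0.0049 plus spatially correlated noise (sd 0.9 m, range
90 m), so the fit recovers the generating coefficients to within sampling
error: interior growth of ~0.64 m over the survey interval, ~1.7 cm less
per metre of initial canopy height, a ridge penalty of ~1.9 cm per TPI
unit, and an edge penalty of ~0.84 m decaying over ~1/c ≈ 200 m.

```r
corrected_intervals(fit, n = 8000, N = 36655)[, c(1, 2, 6, 7)]
#>   parameter estimate lower_corrected upper_corrected
#> 1     beta0  0.64172         0.61976         0.66367
#> 2  beta_tpi -0.01862        -0.02052        -0.01673
#> 3  beta_tch -0.01723        -0.01772        -0.01675
#> 4         b  0.84438         0.81106         0.87770
#> 5         c  0.00489         0.00439         0.00539

edge_penetration_distance(fit$coefficients, tpi = 0, tch_2014 = 5)
#> [1] 85.6   # metres from the edge at which net change reaches zero
```

`subset_ensemble()` runs the 24 × {3000, 4000, 5000}-pixel stability
analysis, `prediction_curves()` evaluates the fitted model for short,
medium and tall canopies (5/20/35 m) on valleys and hilltops (TPI −8.2 and
9.0), and `run_pipeline()` drives scene → terrain → filtering ledger →
ensemble → curves from a single YAML-round-trippable `run_config()`. A thin
CLI over these functions ships in `inst/scripts/canopyedge-cli.R`.

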