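# sfcsample

Spaceborne-lidar height archives (GLAS-style campaigns) sample forests in
discrete shots strung along orbital ground tracks whose density varies
arbitrarily across any region — a spatial pattern that is neither random
nor recognizably systematic, so it supports no defensible inventory
variance. `sfcsample` is for forest-carbon statisticians who want to use
such an archive anyway: it extracts a subset of shots that can justifiably
be treated as a **simple random sample** and turns it into an estimate of
mean aboveground biomass density (Mg/ha) with an honest standard error.

The method, per domain:

1. **Tessellation by space-filling curve.** The forest pixels of an
   equal-area land-cover mask are ordered along a fractal Peano curve
   (Hilbert optional), mapping the 2-D domain onto a 1-D "number line"
   that preserves spatial locality. The line is cut into the smallest
   equal-length segments `l` (searched over every length and every
   looping offset) such that each of the `n = floor(N/l)` segments —
   equal-area, spatially compact cells — contains at least one
   quality-filtered shot. One shot per segment is drawn uniformly at
   random: the application sample S1, spatially balanced yet locally
   arbitrary, the same design argument national forest inventories use
   for their hexagon frames.

2. **Model-based estimation.** A training sample S2 of co-located field
   plots and lidar heights fits a polynomial height–biomass regression
   (default `Y = beta x^2 + eps`, no intercept). The estimate is the mean
   of model predictions over the n S1 heights,

       ybar = (1/n) sum Yhat_i,

   with variance the sum of a **sampling** summand `s^2(Yhat)/n` (the SRS
   variance of the mean prediction) and a **model** summand
   `sum_kl Cov(beta_k, beta_l) xbar*_k xbar*_l` propagating parameter
   uncertainty through the S1 design moments — for the default model,
   `Var(beta) * mean(x^2)^2`.

A synthetic-data generator (`sim_config()`, `simulate_scene()`) emulates
the whole setting — clustered forest mask, correlated height field,
inclined shot tracks, co-located training plots — and
`run_monte_carlo()` validates the estimator's frequentist calibration
end-to-end. See the vignette in `vignettes/` for the model, its
assumptions, and the design choices.

## Worked example

```r
library(sfcsample)

cfg   <- sim_config()                      # 60x60 grid of 230 m pixels, 20 tracks
scene <- simulate_scene(cfg, 42)           # mask + height field + shots
paths <- write_scene(scene, "demo", seed = 42)

est <- run_pipeline(run_config(
  mask = paths[["mask"]], shots = paths[["shots"]],
  training = paths[["training"]], out_dir = "demo/out",
  forest_classes = 1, seed_collapse = 1, seed_draw = 2))
```

which logs and prints:

```
mask: 60 x 60 pixels @ 230 m, N = 1980 forest pixels
shots: 429 retained after quality/domain filtering
order: peano curve, level 4
segment: l = 80 pixels, offset = 1525, n = 24 segments, remainder = 60
sample: 323 shot pixels -> S1 of n = 24
fit: m = 35 plots, MSE = 1210.34, dof = 34
estimate: 287.44 Mg/ha, SE 17.54 (sampling 280.31 + model 27.48)
<biomass_estimate> mean biomass density = 287.44 Mg/ha (SE 17.54)
  variance = 280.31 (sampling) + 27.48 (model) = 307.79
  n (S1) = 24, m (S2) = 35
```

Reading: the 1,980 forest pixels were cut into 24 segments of 80 pixels
(~423 ha each); one shot per segment became the sample whose predicted
biomass averages 287.44 Mg/ha. Of the total variance 307.79 (Mg/ha)^2,
280.31 comes from having only 24 sample cells and 27.48 from the
uncertainty of the fitted coefficient. The scene's true mean — known
because the scene is synthetic — is 287.76 Mg/ha, well inside one
standard error. Artifacts (S1 CSV, segmentation JSON, segment-membership
grid, estimate report with seeds and config hash, run log) land in
`demo/out/`.

A thin command-line wrapper with `run`, `simulate`, `mask`, `order`,
`segment`, `sample`, `fit`, and `estimate` subcommands is installed at
`inst/cli/sfcsample`.

The scale of a real statewide campaign (1.6 million pixels, 182 cells of
9,054 pixels, 35 training plots) is documented in
`california_reference()`.

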