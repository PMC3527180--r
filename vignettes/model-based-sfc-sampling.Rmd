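---
title: "Space-filling-curve sampling and model-based biomass estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-filling-curve sampling and model-based biomass estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spaceborne lidar instruments such as GLAS (the full-waveform altimeter that
flew on ICESat, 2002-2008) measured canopy structure in discrete ~65 m
footprints ("shots") laid ~172 m apart along orbital ground tracks. Shot
heights correlate strongly with aboveground biomass, so the archive is an
attractive basis for a globally consistent forest biomass inventory. The
obstacle is the acquisition pattern: track density varies arbitrarily over
any region of interest, so the shots form neither a random nor a
recognizable systematic sample, and without an identifiable design there is
no defensible variance for an inventory estimate.

`sfcsample` implements a remedy: select a subset of shots that can
justifiably be treated as a simple random sample (SRS), in the spirit of
the US national forest inventory's hexagon frame (one plot retained at
random per equal-area cell), and estimate mean aboveground biomass density
with a model-based estimator whose variance separates sampling uncertainty
from model uncertainty.

## The sampling design

1. **Order the domain.** The forest domain is a binary mask on a projected
   equal-area grid (230 m pixels in the motivating application, chosen to
   sit near the lidar field of view). A fractal space-filling curve — the
   base-3 serpentine Peano curve by default, a base-2 Hilbert curve as an
   alternative behind the same contract — is passed through every pixel of
   the grid, and the forest pixels are read off in visit order. Because
   consecutive curve positions are adjacent pixels, an interval of the
   resulting "number line" is a spatially compact, contiguous patch, and
   equal-length intervals have exactly equal area.

2. **Flag shot-bearing positions.** Quality-failed shots and shots off the
   forest mask are dropped; where several shots share a pixel one is kept
   at random (each with probability 1/k). Every number-line position is
   then flagged by whether its pixel holds a shot.

3. **Tessellate.** The line is cut into `n = floor(N / l)` contiguous
   segments of equal length `l`, requiring at least one shot-bearing
   position per segment. The search scans lengths upward from half the
   longest circular shotless gap (no shorter length can tile the gap) and,
   at each length, all `N` rotation offsets, looping the end of the line
   back to its start; the first viable `(l, s)` — smallest `l`, then
   smallest offset — is the solution, and the trailing `N - n*l` remainder
   is dropped. Termination is guaranteed because `l = N` is always viable.

4. **Draw.** One shot-bearing pixel is drawn uniformly at random in each
   segment: the application sample S1, one height per equal-area cell,
   spatially balanced but locally arbitrary — the same design argument the
   national inventory uses to treat its sample as SRS.

## The estimator

Biomass is related to the lidar height covariate x by a polynomial
regression chosen by the user,

    Y = sum_j beta_j x^j + eps,   eps ~ N(0, sigma^2),

with the single-term quadratic no-intercept form `Y = beta x^2 + eps` as
the default: a forested plot with no height should carry no biomass, and in
the motivating application a linear term added nothing (the package
compares nested forms via the conditional R^2,
`1 - SSE_full / SSE_reduced`). The model is fit by ordinary least squares
on a training sample S2 of co-located field plots and lidar heights —
under the Gaussian error model OLS is the maximum-likelihood fit — with
residual mean square `MSE = SSE / (m - p)` and the standard parameter
covariance `MSE (X'X)^{-1}`, which for the single-term model collapses to
`MSE / sum(x^4)`.

The population mean is estimated by averaging model predictions over the n
S1 heights. Its variance has two summands:

* **sampling**: `s^2(Yhat) / n`, the SRS variance of a mean of n
  predictions (a finite-population correction is available but off by
  default; in the intended use n/N is a few parts in ten thousand);
* **model**: `sum_k sum_l Cov(beta_k, beta_l) xbar*_k xbar*_l`, the
  parameter covariance propagated through the S1 design moments
  `xbar*_k = mean(x^k)`; for the default model this is
  `Var(beta) * mean(x^2)^2`.

The standard error is the square root of their sum, computed from
unrounded intermediates. S1 heights above the training maximum are
predicted anyway — the model is assumed valid for the whole population —
but are listed in a warning and in the result object, since extrapolation
beyond the training range is the main practical risk of the approach. The
estimator carries an unobservable bias term (the population mean of the
model errors), zero in expectation under the model; it is acknowledged
here and not estimated.

## What the synthetic generator emulates

No campaign data ship with the package, so `sim_config()` /
`simulate_scene()` generate study conditions with the structure the method
assumes:

* a clustered binary forest mask (smoothed Gaussian field thresholded at
  the exact forest fraction; default 55% of a 60 x 60 grid of 230 m
  pixels, ~1.5 km patches);
* a spatially correlated Lorey's-height field, piecewise constant within
  pixels (mean 27 m, sd 5.5 m, 700 m correlation length by default,
  truncated at zero). Heights are deliberately defined on the pixel grid:
  a shot reads the height of the pixel it falls in, so the population
  truth `mean(beta x^2)` over forest pixels is exactly the quantity the
  estimator targets and co-located shots agree by construction;
* straight ground tracks at azimuth 94 degrees (or its mirror), shots
  every 172 m, 5% of shots failing quality. Uniformly random track
  offsets already produce the motivating pathology — per-region shot
  counts with a coefficient of variation near 1, nothing like SRS — and
  an optional cluster knob (`n_track_clusters`) concentrates tracks into a
  few corridors for stress testing;
* a training sample of 35 plots hosted by randomly chosen shots, centers
  jittered uniformly within 120 m; the plot reads the height at its
  jittered center and generates biomass from that height, so the
  height-biomass pairs satisfy the model exactly while carrying realistic
  plot-to-shot co-location offsets (`beta = 0.3717` Mg/ha per m^2,
  `sigma = 40` Mg/ha, small enough that zero-truncation touches well under
  1% of draws at default heights).

What it does **not** emulate: orbital mechanics and cloud geometry,
waveform physics and height-retrieval error (heights are treated as exact,
as the estimator assumes), land-cover misclassification, and any real
biomass allometry; passing tests therefore demonstrate the correctness and
calibration of the sampling-and-estimation machinery under its own
assumptions, not the field accuracy of a particular biomass model.

## Frequentist validation and its regime

`run_monte_carlo()` repeats the whole chain on freshly simulated scenes —
new landscape, heights, tracks, shot collapse, S1 draw, training noise
each replicate — and compares each estimate with that replicate's own
population truth. Regenerating the scene is essential: conditioning on a
single fixed scene would hold the shot frame's chance deviation from the
population mean fixed, a constant offset no number of replicates averages
away, and would make any bias check meaningless while leaving coverage at
the mercy of one landscape draw.

The calibration check uses a configuration in which the design argument
holds exactly: `height_correlation_length = 0` (pixel heights independent,
so one draw per segment from the shot-bearing frame is precisely an SRS of
pixel values) and `n_tracks = 40` (about 90 segments, enough that the
nominal `+/- 1.96 SE` normal interval is appropriate; at materially
smaller sample sizes the small-sample effect of the estimated SE erodes
coverage below nominal). Under these conditions 1000 replicates give
95% intervals covering the truth at the nominal rate and an estimator bias
indistinguishable from zero — the acceptance suite asserts coverage in
[0.93, 0.97] and |bias| within 3 Monte Carlo standard errors.

Under the realistic default conditions (spatially correlated heights) the
same interval is mildly *conservative*: one-per-segment selection is
spatially stratified, so the SRS variance formula retains between-segment
variance the design has already removed. With tracks clustered into a few
corridors (`n_track_clusters > 0`) whole regions go unsampled and the SRS
treatment itself breaks down — intervals can undercover badly. That is the
method's real boundary: it assures relative spatial balance only where the
shot archive covers the domain, a caveat that applies equally to the real
archive.

## Numerical and convention choices

* Pixels are indexed 1-based `(row, col)`, row-major, row 1 at the top,
  with half-open footprints: a point on a shared edge belongs to exactly
  one pixel, and the far right/bottom boundary of the grid is outside it.
* Raster I/O uses the plain-text ESRI ASCII grid format; cell sizes below
  1 (degree-like) are rejected because the method requires equal-area
  meter-unit pixels. Nearest-neighbor is the only resampling offered —
  the one class-preserving choice for categorical cover codes.
* The curve is anchored at the grid's top-left corner with a fixed
  generator orientation and the grid embedded in the smallest covering
  curve square; anchoring is arbitrary but frozen for reproducibility.
* The segmentation search prunes candidate lengths with the exact
  longest-gap bound `g < 2l - 1 + (N mod l)` under the circular
  convention: the classic "half the longest gap" starting point is only a
  heuristic once offsets loop and a remainder is dropped, because the
  remainder can absorb part of the gap — enumeration on small lines
  confirms minimal lengths strictly below half the gap exist. Ties among
  viable offsets at the minimal length break to the smallest offset,
  deterministically.
* The two randomized stages (pixel collapse, segment draw) run on
  independent seeded streams, so either can be re-randomized alone, and
  every artifact embeds its seeds and a hash of its configuration.
* Degenerate inputs fail loudly: an empty forest domain, a shotless number
  line, fewer training plots than parameters, and a rank-deficient power
  basis are all errors, not silent fallbacks.

## Problem sizes

The packaged study conditions run a 3,600-pixel scene (~2,000 forest
pixels, ~40-90 segments), sizes at which the full chain takes well under a
second and the 1000-replicate validation a few minutes; the motivating
statewide application (1.6 million pixels, 182 segments of 9,054 pixels)
is documented in `california_reference()` for scale. The segmentation
search is exact — every candidate length from the gap bound upward, every
rotation offset — as in the original procedure, and its cost on the
packaged scenes is negligible; for very large domains the offset scan is
the quadratic term to watch.

## Known limitations

* The design-equivalence claim — that one shot per equal-area cell may be
  treated as SRS — is adopted from inventory precedent and validated
  empirically here, not proven; under strong spatial structure it is
  conservative, under incomplete track coverage it fails.
* Lorey's heights are taken as error-free covariates; height-retrieval
  error would propagate into both the fitted model and the predictions.
* Model-form misspecification is outside the variance: the estimator
  assumes the chosen polynomial is correct.
* No spatial autocorrelation is modeled among S1 elements.
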