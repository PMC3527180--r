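#' Benchmark figures from the California GLAS campaign
#'
#' The headline numbers of the statewide California application that this
#' method was developed for, kept here as a documented benchmark: the
#' model-based estimate and its variance decomposition, the fitted model,
#' the tessellation geometry, the spatial dispersion of the sample, and the
#' national-forest-inventory (FIA) design-based estimate it was compared
#' against. The original campaign inputs (the GLAS shot archive and the 35
#' co-located field plots) are not distributed, so these figures cannot be
#' recomputed here; they document the scale of a real application and their
#' internal arithmetic is checked in the test suite.
#'
#' @return A named list:
#' \describe{
#'   \item{estimate_mg_ha, se_mg_ha}{Mean biomass density estimate and its
#'     standard error (211.11, 20.70 Mg/ha).}
#'   \item{sampling_summand, model_summand}{The two variance components
#'     (241.00 and 186.31 (Mg/ha)^2).}
#'   \item{beta, v_beta}{Fitted quadratic coefficient 0.3717 Mg/ha per m^2
#'     and its estimated variance 0.0005776397.}
#'   \item{r2_no_intercept, r2_intercept, r2_conditional}{Fit diagnostics
#'     (0.87 uncentered; 0.64 for the intercept model; 0.001 conditional).}
#'   \item{n_segments, segment_length_px, resolution_m}{182 tessellation
#'     cells of 9054 pixels at 230 m.}
#'   \item{n_shot_pixels, n_population_px}{About 102,000 shot-bearing
#'     pixels of about 1.6 million forest pixels.}
#'   \item{mean_shots_per_cell}{Average shots per tessellation cell (560).}
#'   \item{cell_area_ha}{Area represented by one cell (48,000 ha).}
#'   \item{nn_mean_km, nn_median_km, nn_min_km}{Nearest-neighbor distance
#'     summary of the sample (19.6, 13.5, 2.4 km).}
#'   \item{s2_size}{35 co-located training plots.}
#'   \item{fia_estimate_mg_ha, fia_se_mg_ha, fia_n_plots,
#'     fia_cost_per_plot_usd, fia_cost_usd}{The design-based benchmark:
#'     208.95 +/- 2.88 Mg/ha from 5261 field plots at ~$2000/plot, about
#'     $10.5 million.}
#' }
#' @export
california_reference <- function() {
  list(
    estimate_mg_ha = 211.11,
    se_mg_ha = 20.70,
    sampling_summand = 241.00,
    model_summand = 186.31,
    beta = 0.3717,
    v_beta = 0.0005776397,
    r2_no_intercept = 0.87,
    r2_intercept = 0.64,
    r2_conditional = 0.001,
    n_segments = 182L,
    segment_length_px = 9054L,
    resolution_m = 230,
    n_shot_pixels = 102000,
    n_population_px = 1.6e6,
    mean_shots_per_cell = 560,
    cell_area_ha = 48000,
    nn_mean_km = 19.6,
    nn_median_km = 13.5,
    nn_min_km = 2.4,
    s2_size = 35L,
    fia_estimate_mg_ha = 208.95,
    fia_se_mg_ha = 2.88,
    fia_n_plots = 5261L,
    fia_cost_per_plot_usd = 2000,
    fia_cost_usd = 10.5e6)
}
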