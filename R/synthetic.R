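#' Configuration for the synthetic lidar-campaign generator
#'
#' Describes a synthetic study scene with the statistical structure the
#' sampling and estimation chain assumes: a clustered binary forest mask, a
#' spatially correlated canopy-height field, straight satellite ground
#' tracks with uneven regional density, heights observed at discrete shots
#' along those tracks, and biomass generated from height by the quadratic
#' no-intercept model `Y = beta x^2 + eps`, `eps ~ N(0, sigma^2)`,
#' truncated at zero.
#'
#' Defaults describe a 60 x 60 scene of 230-m pixels (a ~13.8 km square),
#' about 55% forested with ~1.5 km cover patches; 20 tracks inclined 94
#' degrees from north with shots every 172 m along track and uniformly
#' random perpendicular offsets, which already yields a strongly uneven
#' shot density (per-region counts with coefficient of variation near 1 -
#' nothing like a simple random sample); setting `n_track_clusters > 0`
#' additionally clumps tracks into a few regional clusters, the stress case
#' where whole regions go unsampled. The height field has mean 27 m, sd
#' 5.5 m and ~700 m correlation length; `beta = 0.3717` Mg/ha per m^2 and
#' `sigma = 40` Mg/ha; 35 training plots co-located within 120 m of a
#' shot.
#'
#' @param n_rows,n_cols Grid dimensions (pixels).
#' @param resolution Pixel size (m).
#' @param forest_fraction Fraction of pixels labeled forest, in (0, 1].
#' @param clustering_scale Correlation length (m) of the mask's underlying
#'   field: the typical forest patch size.
#' @param n_tracks Number of ground tracks crossing the scene.
#' @param along_track_spacing Shot spacing along a track (m).
#' @param track_inclination Track azimuth (degrees clockwise from north);
#'   each track is randomly ascending (`inc`) or descending (`360 - inc`).
#' @param n_track_clusters,track_cluster_sd Number of regional track
#'   clusters and the sd (m) of track offsets around a cluster center;
#'   `n_track_clusters = 0` spreads tracks uniformly.
#' @param height_mean,height_sd,height_correlation_length Mean (m), sd (m),
#'   and correlation length (m) of the Lorey's-height field (truncated at
#'   0); a correlation length of 0 gives spatially unstructured
#'   (pixel-independent) heights, the regime in which the one-per-segment
#'   draw is exactly equivalent to simple random sampling of pixel values.
#' @param beta_true True quadratic coefficient (Mg/ha per m^2).
#' @param sigma_true Residual sd of the biomass model (Mg/ha).
#' @param s2_size Number of co-located training plots.
#' @param coloc_radius Maximum distance (m) between a training plot center
#'   and its host shot.
#' @param quality_fail_rate Fraction of shots carrying a failing quality
#'   flag (clouds, atmospheric anomalies).
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(n_rows = 60, n_cols = 60, resolution = 230,
                       forest_fraction = 0.55, clustering_scale = 1500,
                       n_tracks = 20, along_track_spacing = 172,
                       track_inclination = 94,
                       n_track_clusters = 0, track_cluster_sd = 2500,
                       height_mean = 27, height_sd = 5.5,
                       height_correlation_length = 700,
                       beta_true = 0.3717, sigma_true = 40,
                       s2_size = 35, coloc_radius = 120,
                       quality_fail_rate = 0.05) {
  cfg <- list(n_rows = n_rows, n_cols = n_cols, resolution = resolution,
              forest_fraction = forest_fraction,
              clustering_scale = clustering_scale,
              n_tracks = n_tracks,
              along_track_spacing = along_track_spacing,
              track_inclination = track_inclination,
              n_track_clusters = n_track_clusters,
              track_cluster_sd = track_cluster_sd,
              height_mean = height_mean, height_sd = height_sd,
              height_correlation_length = height_correlation_length,
              beta_true = beta_true, sigma_true = sigma_true,
              s2_size = s2_size, coloc_radius = coloc_radius,
              quality_fail_rate = quality_fail_rate)
  stopifnot(cfg$forest_fraction > 0, cfg$forest_fraction <= 1,
            cfg$resolution > 0, cfg$along_track_spacing > 0,
            cfg$clustering_scale > 0, cfg$height_correlation_length >= 0,
            cfg$s2_size >= 2, cfg$coloc_radius >= 0,
            cfg$sigma_true >= 0, cfg$n_tracks >= 1,
            cfg$quality_fail_rate >= 0, cfg$quality_fail_rate < 1)
  structure(cfg, class = "sim_config")
}

# Standardized Gaussian random field on an nr x nc torus: white noise
# circularly convolved (via FFT) with a Gaussian kernel of sd `range_px`
# pixels, then rescaled to mean 0, sd 1.
gaussian_field <- function(nr, nc, range_px) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range_px <= 0) return(z)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  K <- exp(-0.5 * outer(dr^2, dc^2, "+") / range_px^2)
  K <- K / sum(K)
  f <- Re(stats::fft(stats::fft(z) * stats::fft(K), inverse = TRUE)) / (nr * nc)
  (f - mean(f)) / stats::sd(f)
}

#' Simulate a clustered binary forest mask
#'
#' Thresholds a smoothed Gaussian random field at the quantile giving the
#' requested forest fraction: the `round(fraction * n_pixels)` cells with
#' the highest field values become forest, so the forest pixel count is
#' exact up to rounding and the cover forms contiguous patches of the
#' configured scale. Deterministic given `seed`.
#'
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @return A [forest_grid].
#' @export
simulate_landscape <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    f <- gaussian_field(config$n_rows, config$n_cols,
                        config$clustering_scale / config$resolution)
    k <- max(1L, round(config$forest_fraction * length(f)))
    thresh <- sort(f, decreasing = TRUE)[k]
    forest_grid(f >= thresh, config$resolution)
  })
}

#' Simulate the canopy-height field
#'
#' A spatially correlated Lorey's-height surface over the whole grid,
#' piecewise constant within pixels: `mean + sd * field`, truncated at 0.
#' Shots and training plots read their heights from this surface, and the
#' true population mean biomass is defined on it.
#'
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @return A numeric matrix of heights (m), dimension `n_rows x n_cols`.
#' @export
simulate_height_field <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    f <- gaussian_field(config$n_rows, config$n_cols,
                        config$height_correlation_length / config$resolution)
    pmax(config$height_mean + config$height_sd * f, 0)  # keeps dim
  })
}

#' Simulate satellite ground tracks and lidar shots
#'
#' Lays `n_tracks` straight lines across the extent at azimuth
#' `track_inclination` or its mirror `360 - track_inclination` (ascending /
#' descending passes), with perpendicular offsets drawn either uniformly or
#' clumped around a few cluster centers to reproduce the uneven regional
#' density of real acquisitions. Shots are placed every
#' `along_track_spacing` meters along each track; shots outside the extent
#' or over non-forest pixels are dropped. Each shot reads its Lorey's
#' height from the height field and receives a quality flag that fails
#' with probability `quality_fail_rate`.
#'
#' @param grid A [forest_grid] (from [simulate_landscape]).
#' @param height_field Height matrix (from [simulate_height_field]).
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @return A shot data frame: `shot_id`, `x`, `y`, `lorey_height_m`,
#'   `quality_ok` (0/1), `track`.
#' @export
simulate_tracks <- function(grid, height_field, config, seed) {
  stopifnot(inherits(grid, "forest_grid"), inherits(config, "sim_config"))
  W <- ncol(grid$mask) * grid$resolution
  H <- nrow(grid$mask) * grid$resolution
  cx <- grid$origin_x + W / 2
  cy <- grid$origin_y - H / 2
  D <- sqrt(W^2 + H^2)
  with_seed(seed, {
    # perpendicular offsets of the track lines from the scene center
    offs <- if (config$n_track_clusters >= 1) {
      centers <- stats::runif(config$n_track_clusters, -D / 2, D / 2)
      centers[sample.int(config$n_track_clusters, config$n_tracks,
                         replace = TRUE)] +
        stats::rnorm(config$n_tracks, 0, config$track_cluster_sd)
    } else {
      stats::runif(config$n_tracks, -D / 2, D / 2)
    }
    ascending <- sample(c(TRUE, FALSE), config$n_tracks, replace = TRUE)
    shots <- vector("list", config$n_tracks)
    for (i in seq_len(config$n_tracks)) {
      az <- if (ascending[i]) config$track_inclination
            else 360 - config$track_inclination
      a <- az * pi / 180
      dir <- c(sin(a), cos(a))        # unit vector, azimuth from north
      perp <- c(cos(a), -sin(a))
      t <- seq(-D / 2, D / 2, by = config$along_track_spacing)
      px <- cx + offs[i] * perp[1] + t * dir[1]
      py <- cy + offs[i] * perp[2] + t * dir[2]
      shots[[i]] <- data.frame(x = px, y = py, track = i)
    }
    shots <- do.call(rbind, shots)
    pix <- locate_shot_pixel(grid, shots$x, shots$y)
    keep <- !is.na(pix[, "row"])
    keep[keep] <- grid$mask[pix[keep, , drop = FALSE]]
    shots <- shots[keep, , drop = FALSE]
    pix <- pix[keep, , drop = FALSE]
    shots$lorey_height_m <- height_field[pix]
    shots$quality_ok <- as.integer(
      stats::runif(nrow(shots)) >= config$quality_fail_rate)
    shots$shot_id <- sprintf("shot%05d", seq_len(nrow(shots)))
    rownames(shots) <- NULL
    shots[c("shot_id", "x", "y", "lorey_height_m", "quality_ok", "track")]
  })
}

#' Generate biomass from height under the quadratic model
#'
#' `Y = beta_true * h^2 + eps`, `eps ~ N(0, sigma_true^2)`, truncated at 0.
#' Deterministic given `seed` (pass `seed = NULL` to draw from the current
#' RNG stream).
#'
#' @param heights Lorey's heights (m).
#' @param beta_true Quadratic coefficient (Mg/ha per m^2).
#' @param sigma_true Residual sd (Mg/ha).
#' @param seed Integer seed, or `NULL`.
#' @return Biomass densities (Mg/ha), same length as `heights`.
#' @export
simulate_biomass <- function(heights, beta_true, sigma_true, seed = NULL) {
  stopifnot(sigma_true >= 0)
  gen <- function() pmax(0, beta_true * heights^2 +
                            stats::rnorm(length(heights), 0, sigma_true))
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Build the co-located training (S2) sample
#'
#' Samples `s2_size` shots without replacement to host field plots. Each
#' plot center is jittered uniformly within a disk of radius
#' `coloc_radius` around its shot, carrying realistic co-location mismatch:
#' the plot's Lorey's height is the height-field value at the plot center
#' (not at the shot), and its biomass is generated from that height under
#' the quadratic model. Deterministic given `seed`.
#'
#' @param shots Filtered shot table (with `x`, `y` columns).
#' @param height_field Height matrix over `grid`.
#' @param grid The [forest_grid].
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @return A training data frame: `plot_id`, `lorey_height_m`,
#'   `biomass_mg_ha`, `shot_id`, `jitter_m`.
#' @export
build_s2 <- function(shots, height_field, grid, config, seed) {
  stopifnot(inherits(grid, "forest_grid"), inherits(config, "sim_config"))
  if (config$s2_size > nrow(shots))
    stop("s2_size (", config$s2_size, ") exceeds the ", nrow(shots),
         " available shots", call. = FALSE)
  with_seed(seed, {
    host <- shots[sample.int(nrow(shots), config$s2_size), , drop = FALSE]
    r <- config$coloc_radius * sqrt(stats::runif(config$s2_size))
    th <- stats::runif(config$s2_size, 0, 2 * pi)
    px <- host$x + r * cos(th)
    py <- host$y + r * sin(th)
    # clamp jittered centers to the extent so every plot reads a height
    eps <- grid$resolution / 1e6
    px <- pmin(pmax(px, grid$origin_x),
               grid$origin_x + ncol(grid$mask) * grid$resolution - eps)
    py <- pmax(pmin(py, grid$origin_y),
               grid$origin_y - nrow(grid$mask) * grid$resolution + eps)
    pix <- locate_shot_pixel(grid, px, py)
    h <- height_field[pix]
    data.frame(plot_id = sprintf("plot%03d", seq_len(config$s2_size)),
               lorey_height_m = h,
               biomass_mg_ha = simulate_biomass(h, config$beta_true,
                                                config$sigma_true),
               shot_id = host$shot_id,
               jitter_m = r)
  })
}

#' Simulate a complete synthetic scene
#'
#' Convenience wrapper: landscape, height field, and shot tracks from one
#' master seed (three sub-seeds are derived from it), plus the true
#' population mean biomass, `mean(beta_true * h^2)` over forest pixels —
#' the estimand every downstream estimate targets.
#'
#' @param config A [sim_config].
#' @param seed Integer master seed.
#' @return A list: `grid`, `height_field`, `shots`, `truth`, `config`.
#' @export
simulate_scene <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 3L))
  grid <- simulate_landscape(config, seeds[1L])
  hf <- simulate_height_field(config, seeds[2L])
  shots <- simulate_tracks(grid, hf, config, seeds[3L])
  truth <- mean(config$beta_true * hf[grid$mask]^2)
  list(grid = grid, height_field = hf, shots = shots, truth = truth,
       config = config)
}

#' Write a synthetic scene in the package's standard input formats
#'
#' Emits the mask (ESRI ASCII grid, forest = 1), the shot table CSV, a
#' training table CSV, and a YAML snapshot of the configuration, so a
#' synthetic run is indistinguishable from a real-data run downstream.
#'
#' @param scene A scene from [simulate_scene].
#' @param dir Output directory (created if needed).
#' @param seed Seed used to draw the training sample.
#' @return Named character vector of the files written, invisibly.
#' @export
write_scene <- function(scene, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mask = file.path(dir, "mask.asc"),
             shots = file.path(dir, "shots.csv"),
             training = file.path(dir, "training.csv"),
             config = file.path(dir, "config.yml"))
  write_forest_mask(scene$grid, paths[["mask"]])
  utils::write.csv(scene$shots[c("shot_id", "x", "y", "lorey_height_m",
                                 "quality_ok")],
                   paths[["shots"]], row.names = FALSE)
  retained <- filter_shots(scene$shots, scene$grid, quiet = TRUE)
  s2 <- build_s2(retained, scene$height_field, scene$grid, scene$config, seed)
  utils::write.csv(s2[c("plot_id", "lorey_height_m", "biomass_mg_ha")],
                   paths[["training"]], row.names = FALSE)
  yaml::write_yaml(c(unclass(scene$config), list(s2_seed = seed)),
                   paths[["config"]])
  invisible(paths)
}

#' Run one synthetic replicate of the full estimation chain
#'
#' Simulates a fresh scene, filters shots, orders the forest pixels,
#' finds the minimal segmentation, collapses co-located shots, draws the
#' one-per-segment S1 sample, builds the S2 training sample, fits the
#' model, and estimates the population mean. The stochastic stages draw
#' their sub-seeds from `seed`.
#'
#' @param config A [sim_config].
#' @param seed Integer seed for the replicate.
#' @return A list: `estimate` (a `biomass_estimate`), `truth` (the scene's
#'   true mean biomass), `n_segments`, `segment_length`, `n_shot_pixels`,
#'   and `N`.
#' @export
simulate_replicate <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 4L))
  scene <- simulate_scene(config, seeds[1L])
  retained <- filter_shots(scene$shots, scene$grid, quiet = TRUE)
  ord <- order_forest_pixels(scene$grid)
  px <- collapse_shots_to_pixels(retained, seeds[2L])
  line <- build_number_line(ord, px)
  sol <- find_minimal_segmentation(line)
  s1 <- draw_s1(sol, line, px, ord, seeds[3L])
  s2 <- build_s2(retained, scene$height_field, scene$grid, config, seeds[4L])
  fit <- fit_biomass_model(s2)
  res <- suppressWarnings(estimate_population_mean(fit, s1$lorey_height_m))
  list(estimate = res, truth = scene$truth,
       n_segments = sol$n_segments, segment_length = sol$segment_length,
       n_shot_pixels = nrow(px), N = n_forest(scene$grid))
}

#' Monte Carlo validation of the estimator's frequentist properties
#'
#' Repeats the whole chain `n_reps` times, each replicate on a freshly
#' simulated scene (landscape, height field, tracks) with fresh shot
#' collapse, S1 draw, and S2 training noise, so the replication averages
#' over every source of randomness the variance estimator is meant to
#' cover. Each replicate's estimate is compared with that replicate's own
#' true population mean, `mean(beta_true * h^2)` over its forest pixels.
#' Reports the bias of the estimator, the Monte Carlo standard error of
#' that bias, the empirical sd of the estimation errors, the average
#' estimated SE, and the coverage of the nominal 95% interval
#' `estimate +/- 1.96 SE`.
#'
#' @param config A [sim_config].
#' @param n_reps Number of replicates (>= 100).
#' @param seed Integer master seed.
#' @return A list: `bias`, `mc_se_of_bias`, `empirical_sd`, `mean_se`,
#'   `coverage`, `n_reps`, `mean_truth`, `mean_n_segments`, and the
#'   per-replicate `estimates`, `ses`, and `truths`.
#' @export
run_monte_carlo <- function(config, n_reps, seed) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 100)
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_reps))
  est <- se <- truth <- nseg <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    r <- simulate_replicate(config, rep_seeds[i])
    est[i] <- r$estimate$mean_estimate
    se[i] <- r$estimate$standard_error
    truth[i] <- r$truth
    nseg[i] <- r$n_segments
  }
  err <- est - truth
  cover <- abs(err) <= 1.96 * se
  list(bias = mean(err),
       mc_se_of_bias = stats::sd(err) / sqrt(n_reps),
       empirical_sd = stats::sd(err),
       mean_se = mean(se),
       coverage = mean(cover),
       n_reps = n_reps,
       mean_truth = mean(truth),
       mean_n_segments = mean(nseg),
       estimates = est, ses = se, truths = truth)
}
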