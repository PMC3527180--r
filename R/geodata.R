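#' Construct a forest grid
#'
#' A `forest_grid` is the estimation domain: a binary forest/non-forest mask
#' on a regular square-pixel grid in a projected, equal-area coordinate
#' system (meter units). The count of forest pixels `N` is the population
#' size used by every downstream step of the sampling and estimation chain.
#'
#' Pixel convention: 1-based `(row, col)`, row-major, row 1 at the top.
#' Pixel `(r, c)` owns the half-open footprint
#' `[origin_x + (c-1)*res, origin_x + c*res)` in x and
#' `(origin_y - r*res, origin_y - (r-1)*res]` read downward from the
#' top-left corner `(origin_x, origin_y)`; half-open footprints guarantee a
#' boundary point is assigned to exactly one pixel.
#'
#' @param mask Logical matrix, `TRUE` = forest.
#' @param resolution Pixel side length in meters (square pixels).
#' @param origin_x,origin_y Projected coordinates (m) of the top-left corner
#'   of pixel (1, 1). Defaults place the lower-left corner at (0, 0).
#' @return A `forest_grid` object.
#' @examples
#' g <- forest_grid(matrix(c(TRUE, FALSE, TRUE, TRUE), 2), resolution = 230)
#' n_forest(g)
#' @export
forest_grid <- function(mask, resolution,
                        origin_x = 0, origin_y = nrow(mask) * resolution) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  if (anyNA(mask)) stop("`mask` must not contain NA", call. = FALSE)
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a single positive number (meters)", call. = FALSE)
  structure(
    list(mask = mask, resolution = as.numeric(resolution),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y)),
    class = "forest_grid")
}

#' @export
print.forest_grid <- function(x, ...) {
  cat(sprintf("<forest_grid> %d x %d pixels @ %g m (%g ha/pixel)\n",
              nrow(x$mask), ncol(x$mask), x$resolution, pixel_area_ha(x)))
  cat(sprintf("  forest pixels N = %d (%.1f%% of grid)\n",
              n_forest(x), 100 * n_forest(x) / length(x$mask)))
  cat(sprintf("  top-left corner: (%g, %g)\n", x$origin_x, x$origin_y))
  invisible(x)
}

#' Number of forest pixels (the population size N)
#' @param grid A `forest_grid`.
#' @return Integer count of `TRUE` pixels.
#' @export
n_forest <- function(grid) {
  stopifnot(inherits(grid, "forest_grid"))
  sum(grid$mask)
}

#' Pixel area in hectares
#' @param grid A `forest_grid`.
#' @return `(resolution / 100)^2`, the area each pixel represents, in ha.
#' @export
pixel_area_ha <- function(grid) {
  stopifnot(inherits(grid, "forest_grid"))
  (grid$resolution / 100)^2
}

#' Locate the pixel containing a point
#'
#' Applies the half-open footprint convention: a point on the shared edge of
#' two pixels belongs to the pixel whose row/col index is larger, and a point
#' on the grid's outer right/bottom boundary is outside the grid. Vectorized
#' over `x` and `y`.
#'
#' @param grid A `forest_grid`.
#' @param x,y Projected coordinates (m).
#' @return A two-column integer matrix `(row, col)`, `NA` where the point
#'   falls outside the grid extent.
#' @export
locate_shot_pixel <- function(grid, x, y) {
  stopifnot(inherits(grid, "forest_grid"))
  res <- grid$resolution
  col <- floor((x - grid$origin_x) / res) + 1
  row <- floor((grid$origin_y - y) / res) + 1
  # y exactly on the top edge belongs to row 1 (the half-open edge runs
  # downward from the origin)
  row[y == grid$origin_y] <- 1L
  out <- (col < 1 | col > ncol(grid$mask) | row < 1 | row > nrow(grid$mask))
  row[out] <- NA_integer_
  col[out] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# ---- ESRI ASCII grid I/O ----------------------------------------------------

# Reads the six-line ESRI ASCII header + data block. Returns the raw integer
# class-code matrix plus geometry; reclassification happens in the caller.
read_esri_ascii <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(head_lines), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  n_header <- sum(keys %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                              "xllcenter", "yllcenter", "cellsize",
                              "nodata_value"))
  for (k in c("ncols", "nrows", "cellsize"))
    if (!k %in% keys) stop("malformed ASCII grid header: missing ", k, call. = FALSE)
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  cellsize <- vals[["cellsize"]]
  if (cellsize < 1)
    stop("cellsize ", cellsize, " looks geographic (degrees); ",
         "a projected equal-area grid with meter units is required",
         call. = FALSE)
  xll <- if ("xllcorner" %in% keys) vals[["xllcorner"]]
         else vals[["xllcenter"]] - cellsize / 2
  yll <- if ("yllcorner" %in% keys) vals[["yllcorner"]]
         else vals[["yllcenter"]] - cellsize / 2
  vals_num <- scan(path, what = numeric(), skip = n_header, quiet = TRUE)
  if (length(vals_num) != nr * nc)
    stop("ASCII grid data block has ", length(vals_num),
         " values, expected ", nr * nc, call. = FALSE)
  data <- matrix(vals_num, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else NA_real_
  list(data = data, resolution = cellsize,
       origin_x = xll, origin_y = yll + nr * cellsize, nodata = nodata)
}

#' Read a forest mask from an ESRI ASCII grid
#'
#' Reads an integer land-cover raster, optionally resamples it to a target
#' resolution, and reclassifies it to a binary forest mask. Resampling is
#' nearest-neighbor, the only class-preserving choice for categorical codes;
#' output dimensions are `round(input_dim * input_res / target_resolution)`.
#' Grids whose cell size is smaller than 1 (degree-sized cells) are rejected:
#' the method requires equal-area pixels in meter units.
#'
#' @param path Path to an ESRI ASCII grid (integer class codes).
#' @param forest_classes Numeric vector of class codes mapped to forest.
#' @param target_resolution Output pixel size in meters; `NULL` keeps the
#'   native resolution.
#' @return A [forest_grid].
#' @export
read_forest_mask <- function(path, forest_classes, target_resolution = NULL) {
  ras <- read_esri_ascii(path)
  codes <- ras$data
  if (!is.na(ras$nodata)) codes[codes == ras$nodata] <- NA_real_
  if (!is.null(target_resolution)) {
    stopifnot(target_resolution > 0)
    codes <- resample_nearest(codes, ras$resolution, target_resolution)
    res <- target_resolution
  } else {
    res <- ras$resolution
  }
  mask <- matrix(codes %in% forest_classes, nrow = nrow(codes))
  if (!any(mask))
    stop("empty domain: no pixel carries a forest class code", call. = FALSE)
  forest_grid(mask, res, origin_x = ras$origin_x, origin_y = ras$origin_y)
}

# Nearest-neighbor categorical resampling: each output pixel center takes the
# value of the input pixel containing it.
resample_nearest <- function(data, in_res, out_res) {
  nr_in <- nrow(data); nc_in <- ncol(data)
  nr_out <- max(1L, as.integer(round(nr_in * in_res / out_res)))
  nc_out <- max(1L, as.integer(round(nc_in * in_res / out_res)))
  centers_r <- ((seq_len(nr_out) - 0.5) * out_res) / in_res
  centers_c <- ((seq_len(nc_out) - 0.5) * out_res) / in_res
  # half-open convention: a center exactly on a shared edge belongs to the
  # higher-index input pixel
  src_r <- pmin(pmax(floor(centers_r) + 1, 1L), nr_in)
  src_c <- pmin(pmax(floor(centers_c) + 1, 1L), nc_in)
  data[src_r, src_c, drop = FALSE]
}

#' Write a forest mask as an ESRI ASCII grid
#'
#' Forest pixels are written as code 1, non-forest as 0, so a round trip
#' through [read_forest_mask] with `forest_classes = 1` reproduces the mask
#' bit-exactly.
#'
#' @param grid A [forest_grid].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forest_mask <- function(grid, path) {
  stopifnot(inherits(grid, "forest_grid"))
  write_esri_ascii(ifelse(grid$mask, 1L, 0L), grid$resolution,
                   grid$origin_x, grid$origin_y, path)
}

write_esri_ascii <- function(data, resolution, origin_x, origin_y, path,
                             nodata = -9999L) {
  nr <- nrow(data); nc <- ncol(data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.6f", origin_x),
    sprintf("yllcorner %.6f", origin_y - nr * resolution),
    sprintf("cellsize %.6f", resolution),
    sprintf("NODATA_value %d", nodata)), con)
  data[is.na(data)] <- nodata
  writeLines(apply(data, 1L, paste, collapse = " "), con)
  invisible(path)
}

# ---- shot and training tables ----------------------------------------------

#' Read and filter a lidar shot table
#'
#' Reads a CSV of lidar footprints (columns `shot_id`, `x`, `y`,
#' `lorey_height_m`, `quality_ok`) and applies the domain filters: shots
#' failing the quality flag, falling outside the grid extent, or landing on a
#' non-forest pixel are dropped. The retained shots are annotated with their
#' pixel `(row, col)`.
#'
#' @param path CSV path.
#' @param grid A [forest_grid] defining the estimation domain.
#' @param quiet Suppress the retained-count message.
#' @return A data frame with columns `shot_id`, `x`, `y`, `lorey_height_m`,
#'   `row`, `col`.
#' @export
read_shot_table <- function(path, grid, quiet = FALSE) {
  stopifnot(inherits(grid, "forest_grid"))
  shots <- utils::read.csv(path, stringsAsFactors = FALSE)
  filter_shots(shots, grid, quiet = quiet)
}

#' Filter an in-memory shot table against the domain
#'
#' @param shots Data frame with columns `shot_id`, `x`, `y`,
#'   `lorey_height_m`, `quality_ok`.
#' @inheritParams read_shot_table
#' @return As [read_shot_table].
#' @export
filter_shots <- function(shots, grid, quiet = FALSE) {
  required <- c("shot_id", "x", "y", "lorey_height_m", "quality_ok")
  missing <- setdiff(required, names(shots))
  if (length(missing))
    stop("shot table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  n_in <- nrow(shots)
  shots <- shots[as.logical(shots$quality_ok), , drop = FALSE]
  if (nrow(shots) && any(!is.finite(shots$lorey_height_m) |
                         shots$lorey_height_m < 0))
    stop("quality-flagged shots must have finite non-negative Lorey's height",
         call. = FALSE)
  px <- locate_shot_pixel(grid, shots$x, shots$y)
  keep <- !is.na(px[, "row"])
  keep[keep] <- grid$mask[px[keep, , drop = FALSE]]
  shots <- shots[keep, , drop = FALSE]
  px <- px[keep, , drop = FALSE]
  if (!nrow(shots))
    stop("no shots in domain after quality and forest filtering", call. = FALSE)
  shots$row <- px[, "row"]
  shots$col <- px[, "col"]
  shots$quality_ok <- NULL
  rownames(shots) <- NULL
  if (!quiet)
    message(sprintf("retained %d of %d shots after quality/domain filtering",
                    nrow(shots), n_in))
  shots
}

#' Read a training-plot table
#'
#' Reads the field-plot training sample: co-located plots carrying both a
#' lidar Lorey's height (m) and a field-measured aboveground biomass density
#' (Mg/ha). Expected CSV columns: `plot_id`, `lorey_height_m`,
#' `biomass_mg_ha`.
#'
#' @param path CSV path.
#' @return A data frame with the three columns above.
#' @export
read_training_table <- function(path) {
  plots <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("plot_id", "lorey_height_m", "biomass_mg_ha")
  missing <- setdiff(required, names(plots))
  if (length(missing))
    stop("training table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(!is.finite(plots$lorey_height_m) | plots$lorey_height_m < 0))
    stop("training Lorey's heights must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(plots$biomass_mg_ha) | plots$biomass_mg_ha < 0))
    stop("training biomass must be finite and >= 0 (Mg/ha)", call. = FALSE)
  plots
}
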