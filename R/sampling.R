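# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps the pixel-collapse and segment-draw
# randomizations independently re-seedable.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)  # force RNG initialization so the state can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Collapse multiple shots per pixel to a single representative
#'
#' Where several lidar shots fall within one pixel, one is chosen uniformly
#' at random as that pixel's representative; pixels with a single shot pass
#' through unchanged. Deterministic given `seed`.
#'
#' @param shots Filtered shot data frame (from [read_shot_table] or
#'   [filter_shots]) with `row`/`col` pixel columns.
#' @param seed Integer seed for the collapse randomization.
#' @return A shot data frame with at most one row per pixel.
#' @export
collapse_shots_to_pixels <- function(shots, seed) {
  if (nrow(shots) == 0L) return(shots)
  stopifnot(all(c("row", "col") %in% names(shots)))
  key <- paste(shots$row, shots$col)
  keep <- with_seed(seed, {
    # a random uniform per shot; the minimum within each pixel wins,
    # giving each of k co-located shots probability 1/k
    u <- runif(nrow(shots))
    ave(u, key, FUN = min) == u
  })
  out <- shots[keep, , drop = FALSE]
  out <- out[!duplicated(paste(out$row, out$col)), , drop = FALSE]  # tie guard
  rownames(out) <- NULL
  out
}

#' Draw the S1 sample: one shot per tessellation segment
#'
#' For every segment of the minimal equal-length segmentation, chooses one
#' shot-bearing pixel uniformly at random among the segment's shot-bearing
#' pixels (each pixel carries exactly one shot after
#' [collapse_shots_to_pixels]). Shots on remainder positions are never
#' selected. Deterministic given `seed`.
#'
#' @param solution A `segment_solution`.
#' @param line The `shot_flag_line` the solution was computed for.
#' @param pixel_shots Pixel-level shot table (one shot per pixel).
#' @param order The `pixel_order` underlying `line`.
#' @param seed Integer seed for the per-segment draw.
#' @return An `s1_sample`: data frame with columns `segment_id`, `shot_id`,
#'   `row`, `col`, `x`, `y`, `lorey_height_m`, and attribute `seed`.
#' @export
draw_s1 <- function(solution, line, pixel_shots, order, seed) {
  stopifnot(inherits(solution, "segment_solution"),
            inherits(order, "pixel_order"))
  if (length(line) != nrow(order) || solution$N != nrow(order))
    stop("line, order, and solution disagree on N", call. = FALSE)
  nr <- attr(order, "grid_dim")[1L]
  key_order <- order$row + (order$col - 1) * nr
  key_shots <- pixel_shots$row + (pixel_shots$col - 1) * nr
  if (anyDuplicated(key_shots))
    stop("pixel_shots has multiple shots in one pixel; run ",
         "collapse_shots_to_pixels() first", call. = FALSE)
  pos <- match(key_shots, key_order)
  if (anyNA(pos))
    stop("shot pixel(s) missing from the pixel order", call. = FALSE)
  seg <- segment_of_position(solution, pos)
  in_seg <- !is.na(seg)
  if (length(unique(seg[in_seg])) != solution$n_segments)
    stop("inconsistent inputs: some segment contains no shot", call. = FALSE)
  chosen <- with_seed(seed, {
    u <- runif(length(seg))
    u[!in_seg] <- Inf
    vapply(split(seq_along(seg)[in_seg], seg[in_seg]),
           function(ix) ix[which.min(u[ix])], integer(1L))
  })
  # split() keys are sorted, so `chosen` is already in segment-id order
  out <- pixel_shots[chosen, , drop = FALSE]
  out <- cbind(segment_id = sort(unique(seg[in_seg])), out)
  rownames(out) <- NULL
  structure(out, class = c("s1_sample", "data.frame"), seed = seed)
}

#' Nearest-neighbor distance summary of a point set
#'
#' Euclidean nearest-neighbor distance for every point, summarized by mean,
#' median, and the overall minimum (the closest pair). Used to characterize
#' the spatial dispersion of the S1 sample.
#'
#' @param x,y Projected point coordinates (m), length >= 2.
#' @return A list with `mean`, `median`, and `min`, in the input units.
#' @export
nn_distance_stats <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  list(mean = mean(nn), median = stats::median(nn), min = min(nn))
}

#' Export an S1 sample
#'
#' Writes the sample CSV plus a JSON sidecar recording the seeds, so a run
#' can be reproduced exactly.
#'
#' @param s1 An `s1_sample` from [draw_s1].
#' @param path Output CSV path (the sidecar gets the extension `.seeds.json`).
#' @param seed_collapse,seed_draw The seeds used upstream.
#' @return `path`, invisibly.
#' @export
write_s1_sample <- function(s1, path, seed_collapse = NA, seed_draw = attr(s1, "seed")) {
  cols <- intersect(c("segment_id", "shot_id", "row", "col", "x", "y",
                      "lorey_height_m"), names(s1))
  utils::write.csv(as.data.frame(s1)[cols], path, row.names = FALSE)
  jsonlite::write_json(list(seed_collapse = seed_collapse, seed_draw = seed_draw),
                       paste0(tools::file_path_sans_ext(path), ".seeds.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
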