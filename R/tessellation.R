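#' Build the shot-flag number line
#'
#' Marks each position of the ordinal number line (the curve-ordered forest
#' pixels) with whether its pixel carries at least one retained lidar shot.
#' This boolean line is the sole input the segmentation search needs.
#'
#' @param order A `pixel_order` from [order_forest_pixels].
#' @param shot_pixels A two-column matrix or data frame of shot-bearing
#'   pixel `(row, col)` positions (duplicates allowed; multiplicity is
#'   ignored here).
#' @return A `shot_flag_line` object: a logical vector of length `N` with
#'   attribute `shot_count`.
#' @export
build_number_line <- function(order, shot_pixels) {
  stopifnot(inherits(order, "pixel_order"))
  shot_pixels <- as.matrix(shot_pixels[, c("row", "col")])
  nr <- attr(order, "grid_dim")[1L]
  key_order <- order$row + (order$col - 1) * nr
  key_shots <- unique(shot_pixels[, "row"] + (shot_pixels[, "col"] - 1) * nr)
  if (!all(key_shots %in% key_order))
    stop("shot pixel(s) not present in the pixel order: shots must lie on ",
         "forest pixels of the same grid", call. = FALSE)
  flags <- key_order %in% key_shots
  structure(flags, class = "shot_flag_line", shot_count = sum(flags))
}

#' @export
print.shot_flag_line <- function(x, ...) {
  cat(sprintf("<shot_flag_line> N = %d positions, %d shot-bearing (%.1f%%)\n",
              length(x), attr(x, "shot_count"),
              100 * attr(x, "shot_count") / length(x)))
  invisible(x)
}

#' Longest run of shotless positions on the number line
#'
#' The longest gap between shots bounds the minimal viable segment length
#' from below: the segmentation search starts at half this gap. With
#' `circular = TRUE` (the convention used by the search, which loops the end
#' of the line back to its start) a trailing run joins a leading run.
#'
#' @param line A `shot_flag_line` (or plain logical vector with >= 1 TRUE).
#' @param circular Should runs wrap end-to-start?
#' @return Integer length of the longest `FALSE` run (0 if every position
#'   carries a shot).
#' @export
longest_shotless_gap <- function(line, circular = TRUE) {
  flags <- as.logical(line)
  if (!any(flags)) stop("no shots on the number line", call. = FALSE)
  if (all(flags)) return(0L)
  r <- rle(flags)
  gaps <- r$lengths[!r$values]
  if (circular && !flags[1L] && !flags[length(flags)] && length(r$values) > 1L) {
    # wrap: first and last runs are both shotless and distinct
    head_gap <- r$lengths[1L]
    tail_gap <- r$lengths[length(r$lengths)]
    gaps <- c(gaps[-c(1L, length(gaps))], head_gap + tail_gap)
  }
  as.integer(max(gaps))
}

# Is segmentation (l, s) viable for shot positions `pos0` (0-based) on a
# line of length N? Segments tile the rotated line; the remainder after
# n*l positions is dropped.
viable_segmentation <- function(pos0, N, l, s) {
  n <- N %/% l
  p <- (pos0 - s) %% N
  seg <- p %/% l
  seg <- seg[seg < n]
  length(unique(seg)) == n
}

#' Find the minimal equal-length segmentation with >= 1 shot per segment
#'
#' Searches for the smallest segment length `l` (and, among viable offsets
#' at that length, the smallest rotation offset `s`) such that cutting the
#' number line into `n = floor(N / l)` contiguous segments of length `l`
#' leaves at least one shot-bearing position in every segment. The trailing
#' `N - n * l` positions (the remainder) are dropped. Offsets are realized
#' by rotating the whole line, looping its end back to its start, so all
#' `N` starting points are structurally identical.
#'
#' Candidate lengths are scanned upward from 1, skipping lengths that
#' cannot work: those with fewer shots than segments, and those failing the
#' longest-gap bound `g < 2l - 1 + (N mod l)` — if the longest circular
#' shotless gap is at least `2l - 1` even after the dropped remainder is
#' placed inside it, some segment falls entirely in the gap at every
#' offset. (Half the longest gap is the classic starting point; the
#' remainder term is what makes the bound exact under rotation with a
#' dropped tail.) The scan always terminates because `l = N` is viable
#' whenever the line carries a shot.
#'
#' @param line A `shot_flag_line` from [build_number_line].
#' @return A `segment_solution` object: list with `segment_length`,
#'   `offset` (0-based rotation), `n_segments`, `remainder`, and `N`.
#' @export
find_minimal_segmentation <- function(line) {
  flags <- as.logical(line)
  N <- length(flags)
  if (!any(flags)) stop("no shots on the number line", call. = FALSE)
  pos0 <- which(flags) - 1L
  g <- if (all(flags)) 0L else longest_shotless_gap(flags, circular = TRUE)
  for (l in 1:N) {
    n <- N %/% l
    if (length(pos0) < n) next  # fewer shots than segments can never work
    if (g >= 2 * l - 1 + N %% l) next  # gap bound: no offset can avoid it
    for (s in 0:(N - 1L)) {
      if (viable_segmentation(pos0, N, l, s)) {
        return(structure(
          list(segment_length = as.integer(l), offset = as.integer(s),
               n_segments = as.integer(n),
               remainder = as.integer(N - n * l), N = as.integer(N)),
          class = "segment_solution"))
      }
    }
  }
  stop("internal error: no viable segmentation found", call. = FALSE)  # nocov
}

#' @export
print.segment_solution <- function(x, ...) {
  cat(sprintf(
    "<segment_solution> l = %d pixels, offset = %d, n = %d segments, remainder = %d (N = %d)\n",
    x$segment_length, x$offset, x$n_segments, x$remainder, x$N))
  invisible(x)
}

#' Map a number-line position to its segment
#'
#' @param solution A `segment_solution`.
#' @param position 1-based position(s) on the number line (1..N).
#' @return Integer segment id(s) in 1..n_segments, or `NA` for positions
#'   that fall in the dropped remainder.
#' @export
segment_of_position <- function(solution, position) {
  stopifnot(inherits(solution, "segment_solution"))
  if (any(position < 1 | position > solution$N))
    stop("position out of range 1..N", call. = FALSE)
  p <- (position - 1L - solution$offset) %% solution$N
  seg <- p %/% solution$segment_length
  seg <- ifelse(seg < solution$n_segments, seg + 1L, NA_integer_)
  as.integer(seg)
}

#' Export a segmentation as JSON and/or a segment-membership grid
#'
#' `write_segmentation` writes the solution parameters as JSON.
#' `segment_raster` materializes segment membership on the grid (segment id
#' per forest pixel, `NA` elsewhere and for remainder pixels), for mapping
#' the tessellation; `write_segment_raster` saves it as an ESRI ASCII grid.
#'
#' @param solution A `segment_solution`.
#' @param path Output path.
#' @return `path` (writers, invisibly); an integer matrix (`segment_raster`).
#' @export
write_segmentation <- function(solution, path) {
  stopifnot(inherits(solution, "segment_solution"))
  jsonlite::write_json(
    solution[c("segment_length", "offset", "n_segments", "remainder", "N")],
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_segmentation
#' @param order The `pixel_order` the solution was computed on.
#' @param grid The matching [forest_grid].
#' @export
segment_raster <- function(solution, order, grid) {
  stopifnot(inherits(solution, "segment_solution"),
            inherits(order, "pixel_order"), inherits(grid, "forest_grid"))
  if (nrow(order) != solution$N)
    stop("pixel order and segmentation disagree on N", call. = FALSE)
  m <- matrix(NA_integer_, nrow(grid$mask), ncol(grid$mask))
  m[cbind(order$row, order$col)] <- segment_of_position(solution, order$ordinal)
  m
}

#' @rdname write_segmentation
#' @export
write_segment_raster <- function(solution, order, grid, path) {
  m <- segment_raster(solution, order, grid)
  write_esri_ascii(m, grid$resolution, grid$origin_x, grid$origin_y, path)
  invisible(path)
}
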