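#' Space-filling-curve ordering of grid pixels
#'
#' The sampling method rests on mapping the 2-D pixels of the forest mask
#' onto a 1-D ordinal "number line" that preserves spatial locality:
#' consecutive positions on the line are adjacent pixels, so equal-length
#' intervals of the line are spatially compact, roughly equal-area clusters
#' of pixels. Two classic self-similar curves are provided behind the same
#' contract: the base-3 serpentine Peano curve (default) and the base-2
#' Hilbert curve.
#'
#' @name sfc
NULL

# Vectorized Peano index. `row`/`col` are 0-based here; callers convert.
#
# The curve on a 3^k grid is built recursively from the 3x3 serpentine
# generator (down the first column, up the second, down the third). The
# sub-curve inside block (br, bc) of the generator is the level-(k-1) curve
# with its columns mirrored when br is odd and its rows mirrored when bc is
# odd; these reflections make the exit cell of each block 4-adjacent to the
# entry cell of the next, so adjacency holds across all scales.
peano_index0 <- function(row, col, level) {
  idx <- numeric(length(row))
  r <- row; c <- col
  s <- 3^level
  for (k in seq_len(level)) {
    s <- s / 3
    br <- r %/% s
    bc <- c %/% s
    gi <- ifelse(bc %% 2 == 0, bc * 3 + br, bc * 3 + (2 - br))
    idx <- idx * 9 + gi
    r <- r %% s
    c <- c %% s
    flip_rows <- bc %% 2 == 1
    flip_cols <- br %% 2 == 1
    r <- ifelse(flip_rows, s - 1 - r, r)
    c <- ifelse(flip_cols, s - 1 - c, c)
  }
  idx
}

# Vectorized Hilbert index on a 2^k grid (standard quadrant-rotation walk),
# 0-based coordinates.
hilbert_index0 <- function(row, col, level) {
  x <- col; y <- row
  d <- numeric(length(x))
  s <- 2^level / 2
  while (s >= 1) {
    rx <- (x %/% s) %% 2
    ry <- (y %/% s) %% 2
    d <- d + s * s * bitwXor(as.integer(3 * rx), as.integer(ry))
    x <- x %% s
    y <- y %% s
    # rotate the quadrant so the sub-curve has canonical orientation:
    # reflect when rx == 1, then transpose, but only in the ry == 0 rows
    refl <- ry == 0 & rx == 1
    xr <- ifelse(refl, s - 1 - x, x)
    yr <- ifelse(refl, s - 1 - y, y)
    swap <- ry == 0
    xn <- ifelse(swap, yr, xr)
    yn <- ifelse(swap, xr, yr)
    x <- xn
    y <- yn
    s <- s / 2
  }
  d
}

curve_side <- function(family, level) {
  if (family == "peano") 3^level else 2^level
}

#' Generate a space-filling curve on a square grid
#'
#' Returns the full visit sequence of the level-`level` curve: a permutation
#' of all cells of the `side x side` grid (`side = 3^level` for Peano,
#' `2^level` for Hilbert) in which every pair of consecutive cells is
#' 4-adjacent.
#'
#' @param level Non-negative integer recursion depth.
#' @param family `"peano"` (base 3, the default) or `"hilbert"` (base 2).
#' @param max_cells Resource cap on the number of cells materialized.
#' @return A `curve_order` object: a list with `level`, `family`, `side`,
#'   and `visits`, a two-column integer matrix of 1-based `(row, col)` in
#'   visit order.
#' @examples
#' pc <- peano_curve(1)
#' pc$visits  # the 3x3 serpentine generator
#' @export
peano_curve <- function(level, family = c("peano", "hilbert"),
                        max_cells = 2^24) {
  family <- match.arg(family)
  stopifnot(length(level) == 1L, level >= 0, level == floor(level))
  side <- curve_side(family, level)
  if (side^2 > max_cells)
    stop("curve at level ", level, " has ", side^2,
         " cells, exceeding max_cells = ", max_cells, call. = FALSE)
  cells <- expand.grid(row = seq_len(side) - 1L, col = seq_len(side) - 1L)
  idx <- if (family == "peano") {
    peano_index0(cells$row, cells$col, level)
  } else {
    hilbert_index0(cells$row, cells$col, level)
  }
  ord <- order(idx)
  structure(
    list(level = as.integer(level), family = family, side = as.integer(side),
         visits = cbind(row = cells$row[ord] + 1L, col = cells$col[ord] + 1L)),
    class = "curve_order")
}

#' @rdname peano_curve
#' @export
hilbert_curve <- function(level, max_cells = 2^24) {
  peano_curve(level, family = "hilbert", max_cells = max_cells)
}

#' @export
print.curve_order <- function(x, ...) {
  cat(sprintf("<curve_order> %s curve, level %d: %d x %d grid, %d cells\n",
              x$family, x$level, x$side, x$side, nrow(x$visits)))
  invisible(x)
}

#' Order the forest pixels of a grid along a space-filling curve
#'
#' Embeds the grid in the smallest curve square covering it (side `3^k`
#' for Peano, `2^k` for Hilbert), anchored at the grid's top-left corner
#' with a fixed generator orientation, and restricts the curve's visit order
#' to the forest pixels. The result is the ordinal number line: position `i`
#' holds the i-th forest pixel the curve passes through. The module is fully
#' deterministic: the same grid always yields the same order.
#'
#' @param grid A [forest_grid].
#' @param family Curve family, `"peano"` or `"hilbert"`.
#' @return A `pixel_order` object: a data frame with columns `ordinal`,
#'   `row`, `col` (one row per forest pixel) and attributes `level`,
#'   `family`, and `grid_dim` (grid dimensions).
#' @export
order_forest_pixels <- function(grid, family = c("peano", "hilbert")) {
  stopifnot(inherits(grid, "forest_grid"))
  family <- match.arg(family)
  which_forest <- which(grid$mask, arr.ind = TRUE)
  if (nrow(which_forest) == 0L)
    stop("empty domain: the mask has no forest pixel", call. = FALSE)
  base <- if (family == "peano") 3 else 2
  level <- 0L
  while (base^level < max(dim(grid$mask))) level <- level + 1L
  idx <- if (family == "peano") {
    peano_index0(which_forest[, 1L] - 1, which_forest[, 2L] - 1, level)
  } else {
    hilbert_index0(which_forest[, 1L] - 1, which_forest[, 2L] - 1, level)
  }
  ord <- order(idx)
  out <- data.frame(ordinal = seq_along(ord),
                    row = as.integer(which_forest[ord, 1L]),
                    col = as.integer(which_forest[ord, 2L]))
  structure(out, class = c("pixel_order", "data.frame"),
            level = level, family = family, grid_dim = dim(grid$mask))
}

#' Export a pixel order to CSV
#'
#' Writes the `ordinal, row, col` table for audit and plotting.
#'
#' @param order A `pixel_order` from [order_forest_pixels].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pixel_order <- function(order, path) {
  stopifnot(inherits(order, "pixel_order"))
  utils::write.csv(as.data.frame(order)[c("ordinal", "row", "col")],
                   path, row.names = FALSE)
  invisible(path)
}
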