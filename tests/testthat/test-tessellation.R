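test_that("the number line flags exactly the shot-bearing positions", {
  m <- matrix(FALSE, 3, 3)
  m[1, ] <- TRUE
  m[2, 1] <- TRUE
  m[3, 1] <- TRUE   # forest = first peano column + top row: 5 pixels
  g <- forest_grid(m, 100)
  ord <- order_forest_pixels(g)
  # shots on the first and last pixels of the order
  first_last <- rbind(ord[1, c("row", "col")], ord[5, c("row", "col")])
  line <- build_number_line(ord, first_last)
  expect_identical(as.logical(line), c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(attr(line, "shot_count"), 2L)
  # duplicates in shot_pixels don't double-count
  line2 <- build_number_line(ord, rbind(first_last, first_last))
  expect_identical(as.logical(line2), as.logical(line))
  # no shots -> all false; every pixel -> all true
  expect_equal(attr(build_number_line(ord, ord[0, c("row", "col")]),
                    "shot_count"), 0L)
  expect_true(all(build_number_line(ord, ord[, c("row", "col")])))
  # shot pixel off the forest mask is a consistency error
  expect_error(build_number_line(ord, data.frame(row = 3L, col = 3L)),
               "not present")
})

test_that("longest shotless gap handles interior, wrapped, and dense lines", {
  expect_equal(longest_shotless_gap(flag_line(c(T, F, F, F, T))), 3L)
  expect_equal(longest_shotless_gap(flag_line(c(T, F, F, F, T)),
                                    circular = FALSE), 3L)
  # wrap joins the trailing run with the leading run
  expect_equal(longest_shotless_gap(flag_line(c(F, F, T, T, F))), 3L)
  expect_equal(longest_shotless_gap(flag_line(c(F, F, T, T, F)),
                                    circular = FALSE), 2L)
  expect_equal(longest_shotless_gap(flag_line(rep(TRUE, 4))), 0L)
  expect_error(longest_shotless_gap(flag_line(rep(FALSE, 3))), "no shots")
  # exhaustive check against rotation: circular gap equals the max
  # non-circular gap over all rotations
  set.seed(11)
  for (i in 1:50) {
    N <- sample(3:20, 1)
    f <- runif(N) < 0.4
    if (!any(f)) f[1] <- TRUE
    rot_max <- max(vapply(0:(N - 1), function(s) {
      longest_shotless_gap(flag_line(f[((seq_len(N) - 1 + s) %% N) + 1]),
                           circular = FALSE)
    }, integer(1)))
    expect_equal(longest_shotless_gap(flag_line(f), circular = TRUE), rot_max)
  }
})

test_that("minimal segmentation matches hand-worked cases", {
  # densest case: every position a shot
  sol <- find_minimal_segmentation(flag_line(rep(TRUE, 12)))
  expect_equal(sol$segment_length, 1L)
  expect_equal(sol$n_segments, 12L)
  expect_equal(sol$remainder, 0L)
  # N = 12, shots every 3 positions: l = 3 at offset 0; l = 1, 2 infeasible
  f <- rep(FALSE, 12)
  f[c(1, 4, 7, 10)] <- TRUE
  sol <- find_minimal_segmentation(flag_line(f))
  expect_equal(sol$segment_length, 3L)
  expect_equal(sol$offset, 0L)
  expect_equal(sol$n_segments, 4L)
  expect_equal(sol$remainder, 0L)
  expect_error(find_minimal_segmentation(flag_line(rep(FALSE, 5))),
               "no shots")
})

test_that("segmentation agrees with the exhaustive oracle on random lines", {
  set.seed(97)
  for (i in 1:200) {
    N <- sample(2:40, 1)
    density <- runif(1, 0.05, 0.9)
    f <- runif(N) < density
    if (!any(f)) f[sample(N, 1)] <- TRUE
    sol <- find_minimal_segmentation(flag_line(f))
    oracle <- brute_force_segmentation(f)
    expect_equal(sol$segment_length, oracle$l)
    expect_equal(sol$offset, oracle$s)
    expect_equal(sol$n_segments, oracle$n)
    # viability, checked directly on the returned solution
    seg <- segment_of_position(sol, which(f))
    expect_setequal(unique(seg[!is.na(seg)]), seq_len(sol$n_segments))
    # arithmetic identity and the longest-gap feasibility bound: a viable
    # length always satisfies g < 2l - 1 + (N mod l), since otherwise some
    # segment would fall entirely inside the gap at every offset
    expect_equal(sol$n_segments * sol$segment_length + sol$remainder, N)
    g <- longest_shotless_gap(flag_line(f), circular = TRUE)
    expect_lt(g, 2 * sol$segment_length - 1 + N %% sol$segment_length)
  }
})

test_that("adding shots never lengthens the minimal segment", {
  set.seed(31)
  for (i in 1:40) {
    N <- sample(5:30, 1)
    f <- runif(N) < 0.25
    if (!any(f)) f[sample(N, 1)] <- TRUE
    l1 <- find_minimal_segmentation(flag_line(f))$segment_length
    f2 <- f
    f2[sample(which(!f2), min(2, sum(!f2)))] <- TRUE
    l2 <- find_minimal_segmentation(flag_line(f2))$segment_length
    expect_lte(l2, l1)
  }
})

test_that("segment_of_position follows the rotation arithmetic", {
  # s = 0, l = 3: 1-based position 5 is the 5th cell -> segment 2
  sol <- manual_solution(l = 3, s = 0, N = 12)
  expect_equal(segment_of_position(sol, 5), 2L)
  # N = 12, l = 5: n = 2, positions 11-12 are remainder
  sol <- manual_solution(l = 5, s = 0, N = 12)
  expect_true(is.na(segment_of_position(sol, 12)))
  expect_true(is.na(segment_of_position(sol, 11)))
  expect_equal(segment_of_position(sol, 10), 2L)
  # wrapped: s = 2, N = 12, l = 3, first position lands in segment 4
  sol <- manual_solution(l = 3, s = 2, N = 12)
  expect_equal(segment_of_position(sol, 1), 4L)
  # oracle: explicit rotation agrees for every position
  rot_oracle <- function(sol, pos) {
    p <- (pos - 1 - sol$offset) %% sol$N
    seg <- p %/% sol$segment_length + 1
    ifelse(seg <= sol$n_segments, seg, NA_integer_)
  }
  for (s in c(0, 2, 7)) {
    sol <- manual_solution(l = 3, s = s, N = 11)
    expect_equal(segment_of_position(sol, 1:11), rot_oracle(sol, 1:11))
  }
  expect_error(segment_of_position(sol, 0), "out of range")
  expect_error(segment_of_position(sol, 12), "out of range")
})

test_that("segmentation exports and the segment raster line up", {
  g <- forest_grid(random_clustered_mask(9, 9, 5), 100)
  ord <- order_forest_pixels(g)
  set.seed(8)
  shots <- ord[runif(nrow(ord)) < 0.4, c("row", "col")]
  if (nrow(shots) == 0) shots <- ord[1, c("row", "col")]
  line <- build_number_line(ord, shots)
  sol <- find_minimal_segmentation(line)
  json <- withr::local_tempfile(fileext = ".json")
  write_segmentation(sol, json)
  back <- jsonlite::read_json(json)
  expect_equal(back$segment_length, sol$segment_length)
  expect_equal(back$n_segments, sol$n_segments)
  ras <- segment_raster(sol, ord, g)
  expect_identical(dim(ras), dim(g$mask))
  expect_true(all(is.na(ras[!g$mask])))
  counts <- table(ras)
  expect_equal(length(counts), sol$n_segments)
  expect_true(all(counts == sol$segment_length))
})
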