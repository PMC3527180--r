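# Shared fixture builders. Everything is generated in code; no data files.

# A forest grid from a character sketch: "#" = forest, "." = open.
sketch_grid <- function(rows, resolution = 230) {
  mask <- do.call(rbind, lapply(rows, function(r) {
    strsplit(r, "")[[1]] == "#"
  }))
  forest_grid(mask, resolution)
}

# Random clustered mask (blocks of forest), deterministic given seed.
random_clustered_mask <- function(nr, nc, seed) {
  set.seed(seed)
  f <- matrix(stats::rnorm(nr * nc), nr, nc)
  # crude 3x3 moving-average smoothing to create patches
  pad <- function(m) m[c(1, 1:nrow(m), nrow(m)), c(1, 1:ncol(m), ncol(m))]
  p <- pad(f)
  sm <- (p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1)] + p[1:nr, 3:(nc + 2)] +
         p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 2:(nc + 1)] + p[2:(nr + 1), 3:(nc + 2)] +
         p[3:(nr + 2), 1:nc] + p[3:(nr + 2), 2:(nc + 1)] + p[3:(nr + 2), 3:(nc + 2)]) / 9
  m <- sm > stats::quantile(sm, 0.45)
  if (!any(m)) m[1, 1] <- TRUE
  m
}

# Shot table data frame in the raw CSV schema.
make_shots <- function(x, y, h = 20, ok = 1L, id = NULL) {
  n <- max(length(x), length(y))
  data.frame(shot_id = if (is.null(id)) sprintf("s%03d", seq_len(n)) else id,
             x = x, y = y,
             lorey_height_m = rep_len(h, n),
             quality_ok = rep_len(ok, n))
}

# A shot_flag_line built directly from a logical vector (bypassing grids)
# for segmentation unit tests.
flag_line <- function(flags) {
  structure(as.logical(flags), class = "shot_flag_line",
            shot_count = sum(flags))
}

# Manual segment_solution for sampling tests.
manual_solution <- function(l, s, N) {
  n <- N %/% l
  structure(list(segment_length = as.integer(l), offset = as.integer(s),
                 n_segments = as.integer(n), remainder = as.integer(N - n * l),
                 N = as.integer(N)),
            class = "segment_solution")
}

# Independent exhaustive segmentation oracle, written directly from the
# definition: explicitly rotate the line, tile segments, test every one.
brute_force_segmentation <- function(flags) {
  N <- length(flags)
  for (l in 1:N) {
    n <- N %/% l
    for (s in 0:(N - 1)) {
      rot <- flags[((seq_len(N) - 1 + s) %% N) + 1]
      ok <- TRUE
      for (k in seq_len(n)) {
        if (!any(rot[((k - 1) * l + 1):(k * l)])) { ok <- FALSE; break }
      }
      if (ok) return(list(l = l, s = s, n = n))
    }
  }
  NULL
}

# Independent normal-equations OLS oracle for the estimator tests.
brute_force_ols <- function(x, y, powers, intercept) {
  pw <- c(if (intercept) 0L, powers)
  X <- sapply(pw, function(j) x^j)
  X <- matrix(X, nrow = length(x))
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  dof <- length(y) - ncol(X)
  mse <- sum(resid^2) / dof
  list(beta = drop(beta), mse = mse, cov = mse * solve(XtX), sse = sum(resid^2))
}
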