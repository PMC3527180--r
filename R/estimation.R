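#' Specify a polynomial height-biomass model
#'
#' The biomass model is a linear regression on powers of Lorey's height x:
#' `Y = sum_j beta_j x^j + eps`, `eps ~ N(0, sigma^2)`. The default
#' specification is the single quadratic term with no intercept
#' (`Y = beta x^2 + eps`), reflecting the assumption that a forested plot
#' with no Lorey's height carries no biomass.
#'
#' @param powers Distinct non-negative integer exponents of the covariate
#'   (an explicit 0 is equivalent to `intercept = TRUE`).
#' @param intercept Include an intercept term (power 0)?
#' @return A `model_spec` object.
#' @examples
#' model_spec(2)                     # Y = beta x^2 + eps
#' model_spec(c(1, 2), intercept = TRUE)
#' @export
model_spec <- function(powers = 2, intercept = FALSE) {
  powers <- as.integer(powers)
  if (length(powers) == 0L || anyNA(powers) || any(powers < 0))
    stop("`powers` must be non-negative integers", call. = FALSE)
  if (0L %in% powers) {
    intercept <- TRUE
    powers <- setdiff(powers, 0L)
  }
  if (anyDuplicated(powers)) stop("`powers` must be distinct", call. = FALSE)
  structure(list(powers = sort(powers), intercept = isTRUE(intercept)),
            class = "model_spec")
}

# All powers including the intercept's 0, in design-matrix column order.
spec_powers <- function(spec) {
  c(if (spec$intercept) 0L, spec$powers)
}

# Design matrix of the power basis at heights `x`.
power_basis <- function(x, spec) {
  pw <- spec_powers(spec)
  X <- vapply(pw, function(j) x^j, numeric(length(x)))
  X <- matrix(X, nrow = length(x))
  colnames(X) <- ifelse(pw == 0, "(Intercept)", paste0("h^", pw))
  X
}

#' Fit the biomass model on the training (S2) sample
#'
#' Ordinary least squares of biomass on the power basis of Lorey's height,
#' via [stats::lm]. Under the model's Gaussian error, OLS coincides with
#' maximum likelihood. The residual mean square uses `m - p` degrees of
#' freedom and the parameter covariance is the standard linear-model
#' estimate `MSE * (X'X)^-1`; for the single-term no-intercept model this
#' collapses to the scalar `MSE / sum(x^4)`.
#'
#' @param training Data frame with columns `lorey_height_m` and
#'   `biomass_mg_ha` (e.g. from [read_training_table]).
#' @param spec A [model_spec].
#' @return A `biomass_fit` object: list with `beta` (named coefficients),
#'   `cov_beta`, `mse`, `dof`, `m`, `sse`, `spec`, `height_range`, and the
#'   `training` data used.
#' @export
fit_biomass_model <- function(training, spec = model_spec(2)) {
  stopifnot(inherits(spec, "model_spec"))
  x <- training$lorey_height_m
  y <- training$biomass_mg_ha
  if (is.null(x) || is.null(y))
    stop("training data must have lorey_height_m and biomass_mg_ha",
         call. = FALSE)
  m <- length(y)
  X <- power_basis(x, spec)
  p <- ncol(X)
  if (m <= p)
    stop("insufficient training data: ", m, " plots for ", p, " parameters",
         call. = FALSE)
  fit <- stats::lm(y ~ X - 1)
  if (fit$rank < p)
    stop("degenerate design: the power basis is rank-deficient on these ",
         "heights", call. = FALSE)
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  sse <- sum(stats::resid(fit)^2)
  # parameter covariance MSE * (X'X)^-1 straight from the QR factors
  # (identical to vcov(fit), but silent for zero-residual fits)
  unscaled <- chol2inv(qr.R(fit$qr))
  piv <- fit$qr$pivot
  unscaled[piv, piv] <- unscaled
  cov_beta <- sse / (m - p) * unscaled
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  structure(
    list(beta = beta, cov_beta = cov_beta,
         mse = sse / (m - p), dof = m - p, m = m, sse = sse,
         spec = spec, height_range = range(x),
         training = data.frame(lorey_height_m = x, biomass_mg_ha = y)),
    class = "biomass_fit")
}

#' @export
print.biomass_fit <- function(x, ...) {
  terms <- paste(sprintf("%.6g %s", x$beta, names(x$beta)), collapse = " + ")
  cat("<biomass_fit> biomass =", terms, "\n")
  cat(sprintf("  m = %d plots, MSE = %.4g (dof = %d)\n", x$m, x$mse, x$dof))
  invisible(x)
}

#' Predict biomass density from Lorey's height
#'
#' @param fit A `biomass_fit`.
#' @param lorey_height Heights (m), all >= 0.
#' @return Predicted biomass densities (Mg/ha).
#' @export
predict_biomass <- function(fit, lorey_height) {
  stopifnot(inherits(fit, "biomass_fit"))
  if (any(lorey_height < 0)) stop("negative Lorey's height", call. = FALSE)
  drop(power_basis(lorey_height, fit$spec) %*% fit$beta)
}

#' Model-based estimate of mean biomass density with two-part variance
#'
#' Applies the fitted model to the application-sample (S1) heights and
#' returns the estimated population mean together with its variance, the
#' sum of two components: a sampling summand, the simple-random-sampling
#' variance of the mean of the n predictions (`s^2(Yhat)/n`, optionally with
#' a finite-population correction), and a model summand propagating the
#' parameter covariance through the S1 design moments,
#' `sum_k sum_l Cov(beta_k, beta_l) * xbar_k * xbar_l` with `xbar_k` the S1
#' mean of `x^k`. For the single-term no-intercept quadratic model the
#' double sum collapses to `Var(beta) * mean(x^2)^2`.
#'
#' S1 heights above the training range are predicted anyway, on the
#' assumption that the model holds for the whole population, but are
#' reported in the result and flagged with a warning.
#'
#' @param fit A `biomass_fit`.
#' @param s1_heights Lorey's heights (m) of the S1 sample.
#' @param fpc Apply the finite-population correction `(1 - n/N)` to the
#'   sampling summand? Off by default: in the intended use n/N is
#'   negligible.
#' @param N Population size (forest pixel count); required when `fpc=TRUE`.
#' @return A `biomass_estimate` object: list with `mean_estimate`,
#'   `sampling_summand`, `model_summand`, `total_variance`,
#'   `standard_error`, `design_moments`, `n`, `m`, and
#'   `extrapolated_heights`.
#' @export
estimate_population_mean <- function(fit, s1_heights, fpc = FALSE, N = NULL) {
  stopifnot(inherits(fit, "biomass_fit"))
  n <- length(s1_heights)
  if (n == 0L) stop("empty S1 sample", call. = FALSE)
  extrap <- sort(s1_heights[s1_heights > fit$height_range[2L]])
  if (length(extrap))
    warning(sprintf(
      "%d S1 height(s) exceed the training maximum %.1f m: %s",
      length(extrap), fit$height_range[2L],
      paste(signif(extrap, 3), collapse = ", ")), call. = FALSE)
  pred <- predict_biomass(fit, s1_heights)
  mean_estimate <- mean(pred)
  sampling <- if (n > 1L) stats::var(pred) / n else 0
  if (fpc) {
    if (is.null(N)) stop("fpc = TRUE requires N", call. = FALSE)
    sampling <- sampling * (1 - n / N)
  }
  X1 <- power_basis(s1_heights, fit$spec)
  moments <- colMeans(X1)
  model <- drop(t(moments) %*% fit$cov_beta %*% moments)
  total <- sampling + model
  structure(
    list(mean_estimate = mean_estimate,
         sampling_summand = sampling,
         model_summand = model,
         total_variance = total,
         standard_error = sqrt(total),
         design_moments = moments,
         n = n, m = fit$m,
         extrapolated_heights = extrap),
    class = "biomass_estimate")
}

#' @export
print.biomass_estimate <- function(x, ...) {
  cat(sprintf("<biomass_estimate> mean biomass density = %.2f Mg/ha (SE %.2f)\n",
              x$mean_estimate, x$standard_error))
  cat(sprintf("  variance = %.2f (sampling) + %.2f (model) = %.2f\n",
              x$sampling_summand, x$model_summand, x$total_variance))
  cat(sprintf("  n (S1) = %d, m (S2) = %d\n", x$n, x$m))
  if (length(x$extrapolated_heights))
    cat(sprintf("  %d S1 height(s) beyond the training range\n",
                length(x$extrapolated_heights)))
  invisible(x)
}

#' Uncentered R-squared of a no-intercept fit
#'
#' For models without an intercept the conventional centered R-squared is
#' not meaningful; the standard convention is `1 - SSE / sum(Y^2)`, the
#' fraction of the raw (uncentered) sum of squares explained. Values from
#' intercept and no-intercept fits are not directly comparable; use
#' [conditional_r_squared] for that comparison.
#'
#' @param fit A `biomass_fit`.
#' @param training Training data; defaults to the data stored in `fit`.
#' @return A fraction in `[0, 1]` for least-squares fits.
#' @export
r_squared_uncentered <- function(fit, training = fit$training) {
  stopifnot(inherits(fit, "biomass_fit"))
  y <- training$biomass_mg_ha
  tss <- sum(y^2)
  if (tss == 0) stop("all-zero responses: R^2 undefined", call. = FALSE)
  sse <- sum((y - predict_biomass(fit, training$lorey_height_m))^2)
  1 - sse / tss
}

#' Conditional R-squared comparing a full and a reduced model
#'
#' `1 - SSE_full / SSE_reduced`: the proportional reduction in residual sum
#' of squares gained by the full model over the reduced one. A value near 0
#' means the extra terms buy essentially nothing.
#'
#' @param full_sse Residual sum of squares of the full model.
#' @param reduced_sse Residual sum of squares of the reduced model (> 0).
#' @return The conditional R-squared.
#' @export
conditional_r_squared <- function(full_sse, reduced_sse) {
  if (reduced_sse <= 0)
    stop("reduced-model SSE must be positive", call. = FALSE)
  1 - full_sse / reduced_sse
}

#' Export an estimate report as JSON
#'
#' @param fit A `biomass_fit`.
#' @param estimate A `biomass_estimate`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_estimate_report <- function(fit, estimate, path) {
  report <- list(
    beta_hat = as.list(fit$beta),
    cov_beta = fit$cov_beta,
    mse = fit$mse,
    dof = fit$dof,
    mean_estimate_mg_ha = estimate$mean_estimate,
    sampling_summand = estimate$sampling_summand,
    model_summand = estimate$model_summand,
    total_variance = estimate$total_variance,
    standard_error = estimate$standard_error,
    n_s1 = estimate$n,
    m_s2 = estimate$m,
    extrapolated_heights = estimate$extrapolated_heights)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
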