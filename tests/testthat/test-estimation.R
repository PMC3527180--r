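train <- function(h, y) data.frame(lorey_height_m = h, biomass_mg_ha = y)

test_that("model_spec validates and normalizes the power basis", {
  sp <- model_spec(2)
  expect_identical(sp$powers, 2L)
  expect_false(sp$intercept)
  # an explicit 0 power is the intercept
  sp <- model_spec(c(0, 2))
  expect_true(sp$intercept)
  expect_identical(sp$powers, 2L)
  expect_error(model_spec(integer(0)), "non-negative")
  expect_error(model_spec(c(2, 2)), "distinct")
  expect_error(model_spec(-1), "non-negative")
})

test_that("an exact quadratic is recovered with zero residual variance", {
  fit <- fit_biomass_model(train(1:3, (1:3)^2), model_spec(2))
  expect_equal(unname(fit$beta), 1)
  expect_equal(fit$mse, 0)
  expect_equal(unname(drop(fit$cov_beta)), 0)
  expect_equal(fit$dof, 2L)
})

test_that("the two-plot toy fit matches exact hand computation", {
  # plots (h, Y) = (1, 2), (2, 4), single quadratic, no intercept:
  # beta = sum(x^2 Y) / sum(x^4) = 18/17, SSE = 16/17, dof = 1,
  # V(beta) = MSE / sum(x^4) = 16/289
  fit <- fit_biomass_model(train(c(1, 2), c(2, 4)), model_spec(2))
  expect_equal(unname(fit$beta), 18 / 17, tolerance = 1e-12)
  expect_equal(fit$mse, 16 / 17, tolerance = 1e-12)
  expect_equal(unname(drop(fit$cov_beta)), 16 / 289, tolerance = 1e-12)
  # and the single-term covariance identity MSE / sum(x^4)
  expect_equal(unname(drop(fit$cov_beta)),
               fit$mse / sum(c(1, 2)^4), tolerance = 1e-12)

  # population estimate on S1 heights {1, 3} (height 3 extrapolates
  # beyond the toy training range; that path is tested separately)
  est <- suppressWarnings(estimate_population_mean(fit, c(1, 3)))
  expect_equal(est$mean_estimate, 90 / 17, tolerance = 1e-12)
  expect_equal(est$sampling_summand, 5184 / 289, tolerance = 1e-12)
  # model summand collapses to V(beta) * mean(x^2)^2 = 16/289 * 25
  expect_equal(est$model_summand, 400 / 289, tolerance = 1e-12)
  expect_equal(est$total_variance, est$sampling_summand + est$model_summand)
  expect_equal(est$standard_error, sqrt(5584 / 289), tolerance = 1e-12)
})

test_that("the fit agrees with brute-force normal equations", {
  set.seed(202)
  specs <- list(model_spec(2), model_spec(c(1, 2)),
                model_spec(c(1, 2), intercept = TRUE),
                model_spec(1, intercept = TRUE))
  for (i in 1:100) {
    sp <- specs[[(i %% 4) + 1]]
    m <- sample(5:20, 1)
    h <- runif(m, 2, 45)
    y <- pmax(0, 0.4 * h^2 + rnorm(m, 0, 25))
    fit <- fit_biomass_model(train(h, y), sp)
    oracle <- brute_force_ols(h, y, sp$powers, sp$intercept)
    expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-10)
    expect_equal(fit$mse, oracle$mse, tolerance = 1e-10)
    expect_equal(unname(fit$cov_beta), unname(oracle$cov), tolerance = 1e-10)
  }
})

test_that("degenerate designs and undersized training sets are rejected", {
  expect_error(fit_biomass_model(train(1, 1), model_spec(2)),
               "insufficient")
  # identical heights make a two-term basis rank deficient
  expect_error(fit_biomass_model(train(c(5, 5, 5), c(9, 10, 11)),
                                 model_spec(c(1, 2))),
               "degenerate|insufficient")
})

test_that("prediction follows the fitted polynomial", {
  fit <- fit_biomass_model(train(c(1, 2), c(2, 4)), model_spec(2))
  fit$beta[] <- 0.3717
  expect_equal(predict_biomass(fit, 20), 148.68)
  expect_equal(predict_biomass(fit, 0), 0)  # no-intercept property
  fit$beta[] <- 1
  expect_equal(predict_biomass(fit, 3), 9)
  expect_error(predict_biomass(fit, -1), "negative")
})

test_that("the generic double-sum equals the collapsed single-term form", {
  set.seed(7)
  for (i in 1:20) {
    h <- runif(12, 5, 40)
    y <- 0.37 * h^2 + rnorm(12, 0, 30)
    fit <- fit_biomass_model(train(h, pmax(y, 0)), model_spec(2))
    s1 <- runif(30, 5, 45)
    est <- suppressWarnings(estimate_population_mean(fit, s1))
    collapsed <- drop(fit$cov_beta) * mean(s1^2)^2
    expect_equal(est$model_summand, collapsed, tolerance = 1e-12)
  }
})

test_that("noiseless training data give exact recovery and no model variance", {
  h <- c(5, 12, 20, 33)
  fit <- fit_biomass_model(train(h, 0.52 * h^2), model_spec(2))
  expect_equal(unname(fit$beta), 0.52, tolerance = 1e-12)
  s1 <- c(8, 15, 25)
  est <- estimate_population_mean(fit, s1)
  expect_equal(est$model_summand, 0, tolerance = 1e-15)
  expect_equal(est$mean_estimate, mean(0.52 * s1^2), tolerance = 1e-12)
})

test_that("the estimate is scale equivariant in the response", {
  set.seed(13)
  h <- runif(10, 5, 40)
  y <- 0.37 * h^2 + rnorm(10, 0, 20)
  s1 <- runif(25, 5, 40)
  c0 <- 3.7
  e1 <- suppressWarnings(
    estimate_population_mean(fit_biomass_model(train(h, y), model_spec(2)), s1))
  e2 <- suppressWarnings(
    estimate_population_mean(fit_biomass_model(train(h, c0 * y), model_spec(2)), s1))
  expect_equal(e2$mean_estimate, c0 * e1$mean_estimate, tolerance = 1e-12)
  expect_equal(e2$sampling_summand, c0^2 * e1$sampling_summand, tolerance = 1e-12)
  expect_equal(e2$model_summand, c0^2 * e1$model_summand, tolerance = 1e-12)
})

test_that("constant S1 heights leave only model variance", {
  fit <- fit_biomass_model(train(c(1, 2, 4), c(2, 4, 15)), model_spec(2))
  est <- estimate_population_mean(fit, c(3, 3, 3))
  expect_equal(est$sampling_summand, 0)
  expect_equal(est$model_summand, drop(fit$cov_beta) * 81, tolerance = 1e-12)
})

test_that("S1 heights beyond the training range are flagged, not truncated", {
  fit <- fit_biomass_model(train(c(10, 20, 30), c(40, 150, 330)),
                           model_spec(2))
  expect_warning(est <- estimate_population_mean(fit, c(15, 35, 44)),
                 "exceed the training maximum")
  expect_identical(est$extrapolated_heights, c(35, 44))
  # prediction still used the extrapolated heights
  expect_equal(est$n, 3L)
  expect_equal(est$mean_estimate,
               mean(predict_biomass(fit, c(15, 35, 44))), tolerance = 1e-12)
  expect_error(estimate_population_mean(fit, numeric(0)), "empty")
})

test_that("the finite-population correction shrinks only the sampling term", {
  fit <- fit_biomass_model(train(c(1, 2), c(2, 4)), model_spec(2))
  e0 <- suppressWarnings(estimate_population_mean(fit, c(1, 3)))
  e1 <- suppressWarnings(
    estimate_population_mean(fit, c(1, 3), fpc = TRUE, N = 10))
  expect_equal(e1$sampling_summand, e0$sampling_summand * (1 - 2 / 10))
  expect_equal(e1$model_summand, e0$model_summand)
  expect_error(suppressWarnings(
    estimate_population_mean(fit, c(1, 3), fpc = TRUE)), "requires N")
})

test_that("R-squared diagnostics behave at their boundary cases", {
  # perfect fit
  fit <- fit_biomass_model(train(1:3, (1:3)^2), model_spec(2))
  expect_equal(r_squared_uncentered(fit), 1)
  # a zero model explains none of the uncentered sum of squares
  fit0 <- fit_biomass_model(train(c(1, 2), c(2, 4)), model_spec(2))
  fit0$beta[] <- 0
  expect_equal(r_squared_uncentered(fit0), 0)
  expect_error(r_squared_uncentered(fit0, train(c(1, 2), c(0, 0))),
               "all-zero")
  # conditional comparison
  expect_equal(conditional_r_squared(5, 5), 0)
  expect_equal(conditional_r_squared(0, 5), 1)
  expect_error(conditional_r_squared(1, 0), "positive")
})

test_that("the estimate report JSON carries the full decomposition", {
  fit <- fit_biomass_model(train(c(1, 2), c(2, 4)), model_spec(2))
  est <- suppressWarnings(estimate_population_mean(fit, c(1, 3)))
  path <- withr::local_tempfile(fileext = ".json")
  write_estimate_report(fit, est, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$mean_estimate_mg_ha, est$mean_estimate)
  expect_equal(rep$sampling_summand + rep$model_summand, rep$total_variance)
  expect_equal(rep$n_s1, 2L)
  expect_equal(rep$m_s2, 2L)
})
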