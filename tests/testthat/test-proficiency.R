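test_that("perfect and anti-correlated forecasts give the boundary values", {
  ens <- make_ensemble(n = 30)
  cv <- windowed_correlation_curve(ens, window_length = 5)
  expect_true(all(abs(cv$mean_proficiency - 1) < 1e-12))
  expect_true(cv$higher_is_better)

  ens_neg <- make_ensemble(n = 30, fc_fun = function(v) -v)
  cv_neg <- windowed_correlation_curve(ens_neg, window_length = 5)
  expect_true(all(abs(cv_neg$mean_proficiency + 1) < 1e-12))
})

test_that("windowed correlation matches the direct-formula oracle", {
  tru <- trajectory(1:5, c(1, 3, 2, 5, 4))
  fc <- trajectory(1:5, c(2, 3, 1, 6, 4))
  cv <- windowed_correlation_curve(forecast_ensemble(tru, fc),
                                   window_length = 5)
  expect_length(cv$mean_proficiency, 1L)
  expect_equal(cv$mean_proficiency,
               oracle_pearson(c(1, 3, 2, 5, 4), c(2, 3, 1, 6, 4)),
               tolerance = 1e-12)
  expect_equal(cv$distances, 3)  # centre of the single window
})

test_that("zero-variance windows propagate as missing, never as zero", {
  tru <- trajectory(1:12, c(rep(5, 6), 1:6))
  fc <- trajectory(1:12, c(1:6, rep(2, 6)))
  cv <- windowed_correlation_curve(forecast_ensemble(tru, fc),
                                   window_length = 5)
  expect_true(anyNA(cv$mean_proficiency))
  expect_false(any(cv$mean_proficiency == 0, na.rm = TRUE))
})

test_that("error metrics recover a constant offset and obey RMSE^2 = MSE", {
  ens <- make_ensemble(n = 25, fc_fun = function(v) v + 2)
  for (m in c("bias", "MAE", "RMSE")) {
    cv <- error_metric_curve(ens, m, window_length = 6)
    expect_true(all(abs(cv$mean_proficiency - 2) < 1e-12), info = m)
    expect_false(cv$higher_is_better)
  }
  mse <- error_metric_curve(ens, "MSE", window_length = 6)
  expect_true(all(abs(mse$mean_proficiency - 4) < 1e-12))

  set.seed(4)
  ens2 <- make_ensemble(n = 40, fc_fun = function(v) v + rnorm(length(v)))
  rmse <- error_metric_curve(ens2, "RMSE", window_length = 10)
  mse2 <- error_metric_curve(ens2, "MSE", window_length = 10)
  expect_equal(rmse$mean_proficiency^2, mse2$mean_proficiency,
               tolerance = 1e-12)
})

test_that("error metrics equal loop-based accumulation on a random pair", {
  set.seed(9)
  tv <- rnorm(10); fv <- rnorm(10)
  ens <- forecast_ensemble(trajectory(1:10, tv), trajectory(1:10, fv))
  for (m in c("bias", "MSE", "RMSE", "MAE")) {
    cv <- error_metric_curve(ens, m, window_length = 5, step = 5)
    expect_equal(cv$mean_proficiency, oracle_error(tv, fv, m, 5, 5),
                 tolerance = 1e-10, info = m)
  }
})

test_that("r-squared is linear-invariant and consistent with correlation", {
  ens <- make_ensemble(n = 20, fc_fun = function(v) 3 + 0.5 * v)
  r2 <- r_squared_curve(ens, window_length = 5)
  expect_true(all(abs(r2$mean_proficiency - 1) < 1e-10))

  set.seed(2)
  ens2 <- make_ensemble(n = 20, fc_fun = function(v) v + rnorm(length(v)))
  r2b <- r_squared_curve(ens2, window_length = 5)
  cb <- windowed_correlation_curve(ens2, window_length = 5)
  expect_equal(r2b$mean_proficiency, cb$mean_proficiency^2,
               tolerance = 1e-12)
  expect_true(all(r2b$mean_proficiency >= 0 & r2b$mean_proficiency <= 1))

  # the sum-of-squares convention penalises the biased forecast
  ens3 <- make_ensemble(n = 20, fc_fun = function(v) v + 5)
  ss <- r_squared_curve(ens3, window_length = 5, convention = "ss")
  sq <- r_squared_curve(ens3, window_length = 5)
  expect_true(all(ss$mean_proficiency < sq$mean_proficiency))
})

test_that("curve aggregation means and percentile bands match a sort oracle", {
  set.seed(7)
  d <- 0:10
  curves <- lapply(1:20, function(i)
    proficiency_curve(d, pmin(1, pmax(-1, exp(-d / 5) + rnorm(11, 0, 0.1))),
                      "correlation", TRUE))
  agg <- aggregate_curves(curves, band = c(0.25, 0.75))
  vals <- do.call(rbind, lapply(curves, `[[`, "mean_proficiency"))
  expect_equal(agg$mean_proficiency, colMeans(vals), tolerance = 1e-12)
  for (j in c(1, 6, 11)) {
    expect_equal(agg$band$lower[j], oracle_percentile(vals[, j], 0.25),
                 tolerance = 1e-12)
    expect_equal(agg$band$upper[j], oracle_percentile(vals[, j], 0.75),
                 tolerance = 1e-12)
  }
  # degenerate cases
  one <- aggregate_curves(curves[[1]])
  expect_equal(one$mean_proficiency, curves[[1]]$mean_proficiency)
  expect_equal(one$band$lower, one$band$upper)
  two <- aggregate_curves(list(
    proficiency_curve(d, rep(0, 11), "correlation", TRUE),
    proficiency_curve(d, rep(1, 11), "correlation", TRUE)))
  expect_true(all(two$mean_proficiency == 0.5))
})

test_that("curve construction enforces its invariants", {
  expect_error(proficiency_curve(c(0, 0, 1), c(1, 1, 1), "correlation", TRUE),
               "strictly increasing")
  expect_error(proficiency_curve(0:2, c(1, 2, 0.5), "correlation", TRUE),
               "outside the range")
  expect_error(proficiency_curve(0:2, c(1, 1, 1), "correlation", TRUE,
                                 replicates = matrix(0, 2, 3)),
               "does not match")
  expect_error(windowed_correlation_curve(make_ensemble(10), window_length = 2),
               "at least 3")
  expect_error(forecast_ensemble(trajectory(1:5, 1:5),
                                 trajectory(2:6, 1:5)),
               "time axis")
})
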