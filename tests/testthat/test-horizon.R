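test_that("threshold crossings follow the first-crossing rules", {
  flat <- proficiency_curve(0:10, rep(1, 11), "correlation", TRUE)
  expect_identical(horizon_from_curve(flat, 0.5)$horizon, Inf)

  lin <- proficiency_curve(0:10, seq(1, 0, by = -0.1), "correlation", TRUE)
  expect_equal(horizon_from_curve(lin, 0.5)$horizon, 5)
  expect_equal(horizon_from_curve(lin, 0.5, interpolation = "step")$horizon, 6)

  # starting on the crossed side gives 0
  low <- proficiency_curve(0:10, seq(0.2, 0, length.out = 11),
                           "correlation", TRUE)
  expect_equal(horizon_from_curve(low, 0.5)$horizon, 0)

  # rises_above: useful region begins at the crossing
  rise <- proficiency_curve(0:10, seq(0.4, 0.9, length.out = 11), "auc", TRUE)
  est <- horizon_from_curve(rise, 0.65, crossing = "rises_above")
  expect_equal(est$horizon, 5)
  never <- proficiency_curve(0:10, rep(0.5, 11), "auc", TRUE)
  expect_identical(
    horizon_from_curve(never, 0.6, crossing = "rises_above")$horizon, Inf)

  expect_error(horizon_from_curve(flat, 2), "outside the range")
  all_na <- proficiency_curve(0:3, c(NA, NA, NA, 0.2), "correlation", TRUE)
  expect_error(horizon_from_curve(all_na, 0.5), "non-missing")
})

test_that("interpolated crossing matches a dense-grid scan on exp(-d/7)", {
  d <- 0:40
  cv <- proficiency_curve(d, exp(-d / 7), "correlation", TRUE)
  got <- horizon_from_curve(cv, 0.5)$horizon
  # oracle: linear interpolation of the sampled curve on a 1e-4 grid
  oracle <- oracle_dense_crossing(function(g) approx(d, exp(-d / 7), g)$y,
                                  0, 40, 0.5)
  expect_equal(got, oracle, tolerance = 1e-3)
  # closed-form cross-check on the underlying curve
  expect_equal(got, 7 * log(2), tolerance = 0.05)
})

test_that("horizon is monotone in the threshold (falls_below)", {
  set.seed(5)
  d <- 0:30
  for (i in 1:10) {
    v <- pmin(1, pmax(-1, exp(-d / runif(1, 3, 12)) + rnorm(31, 0, 0.05)))
    cv <- proficiency_curve(d, v, "correlation", TRUE)
    hs <- sapply(c(0.2, 0.4, 0.6, 0.8),
                 function(th) horizon_from_curve(cv, th)$horizon)
    expect_true(all(diff(hs) <= 1e-9))
  }
})

test_that("horizon distributions summarise replicates with infinities ranked on top", {
  d <- 0:10
  same <- replicate(3, proficiency_curve(d, seq(1, 0, by = -0.1),
                                         "correlation", TRUE),
                    simplify = FALSE)
  hd <- horizon_distribution(same, 0.5)
  expect_equal(hd$median, 5)
  expect_equal(unname(hd$band), c(5, 5))

  # odd-count median
  mk <- function(h) proficiency_curve(d, pmax(0, 1 - d * 0.5 / h),
                                      "correlation", TRUE)
  hd2 <- horizon_distribution(lapply(c(2, 4, 6, 8, 10), mk), 0.5)
  expect_equal(hd2$median, 6)

  # sort-oracle agreement on 100 noisy decay curves
  curves <- gen_replicate_curves(5, "exponential", noise_sd = 0.05,
                                 n_reps = 100, seed = 31)
  hd3 <- horizon_distribution(curves, 0.5, band = c(0.55, 0.65))
  hs <- sapply(curves, function(cu) horizon_from_curve(cu, 0.5)$horizon)
  expect_equal(hd3$median, oracle_percentile(hs, 0.5), tolerance = 1e-12)
  expect_equal(unname(hd3$band),
               c(oracle_percentile(hs, 0.55), oracle_percentile(hs, 0.65)),
               tolerance = 1e-12)

  # majority-infinite medians are infinite
  curves_inf <- c(same, replicate(4, proficiency_curve(
    d, rep(0.9, 11), "correlation", TRUE), simplify = FALSE))
  hd4 <- horizon_distribution(curves_inf, 0.5)
  expect_identical(hd4$median, Inf)
  expect_equal(hd4$n_infinite, 4L)
  expect_equal(hd4$mean_finite, 5)
})

test_that("fitted decay horizons recover noiseless crossings", {
  d <- 0:29
  cv <- proficiency_curve(d, exp(-d / 7), "r_squared", TRUE)
  est <- fit_decay_curve_horizon(cv, "exponential", 0.6)
  expect_equal(est$horizon, 7 * log(1 / 0.6), tolerance = 1e-6)

  lg <- proficiency_curve(d, 0.9 / (1 + exp((d - 12) / 3)), "r_squared", TRUE)
  est_lg <- fit_decay_curve_horizon(lg, "logistic", 0.6)
  expect_equal(est_lg$horizon, 12 + 3 * log(0.9 / 0.6 - 1), tolerance = 1e-6)

  sp <- fit_decay_curve_horizon(cv, "monotone_spline", 0.6)
  expect_equal(sp$horizon, 7 * log(1 / 0.6), tolerance = 1e-3)

  # proficiency everywhere above the threshold: infinite horizon
  hi <- proficiency_curve(d, 0.95 - 0.001 * d, "r_squared", TRUE)
  expect_identical(fit_decay_curve_horizon(hi, "exponential", 0.2)$horizon,
                   Inf)
})

test_that("fitted-horizon confidence intervals behave like confidence intervals", {
  true_h <- 7 * log(1 / 0.6)
  cover <- logical(200); inside <- logical(200)
  set.seed(123)
  for (s in 1:200) {
    d <- seq(0, 29, length.out = 30)
    v <- pmin(1, pmax(-1, exp(-d / 7) + rnorm(30, 0, 0.05)))
    cv <- proficiency_curve(d, v, "correlation", TRUE)
    est <- fit_decay_curve_horizon(cv, "exponential", 0.6)
    cover[s] <- est$interval[1] <= true_h && true_h <= est$interval[2]
    inside[s] <- est$interval[1] <= est$horizon &&
      est$horizon <= est$interval[2]
  }
  expect_true(all(inside))
  expect_gte(mean(cover), 0.8)
})

test_that("blind spots partition the support and match a dense scan", {
  # U-shaped dip below the threshold
  d <- seq(0, 10, by = 0.05)
  f <- function(g) 1 - 0.8 * exp(-(g - 5)^2 / 2)
  cv <- proficiency_curve(d, f(d), "correlation", TRUE)
  bad <- detect_blind_spots(cv, 0.5)
  expect_equal(nrow(bad), 1L)
  expect_equal(bad$start, oracle_dense_crossing(f, 0, 10, 0.5),
               tolerance = 1e-3)
  # closed form for the dip edges: 5 -+ sqrt(2 log(1.6))
  expect_equal(bad$start, 5 - sqrt(2 * log(1.6)), tolerance = 1e-3)
  expect_equal(bad$end, 5 + sqrt(2 * log(1.6)), tolerance = 1e-3)

  # monotone decay: single trailing bad interval
  d2 <- 0:10
  mono <- proficiency_curve(d2, seq(1, 0, by = -0.1), "correlation", TRUE)
  bad2 <- detect_blind_spots(mono, 0.5)
  expect_equal(bad2, data.frame(start = 5, end = 10))

  # entirely above threshold: empty
  hi <- proficiency_curve(d2, rep(0.9, 11), "correlation", TRUE)
  expect_equal(nrow(detect_blind_spots(hi, 0.5)), 0L)

  # good/bad intervals partition [0, 10] exactly
  good <- detect_blind_spots(cv, 0.5, side = "good")
  pieces <- rbind(bad, good)
  pieces <- pieces[order(pieces$start), ]
  expect_equal(pieces$start[1], 0)
  expect_equal(pieces$end[nrow(pieces)], 10)
  expect_equal(pieces$start[-1], pieces$end[-nrow(pieces)], tolerance = 1e-12)
})
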