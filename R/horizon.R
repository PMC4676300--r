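#' Forecast horizon of a proficiency curve
#'
#' The forecast horizon is the first distance at which a proficiency curve
#' crosses the forecast proficiency threshold in the stated direction:
#' `"falls_below"` for metrics that decay with distance (the useful region
#' ends at the horizon), `"rises_above"` for curves that improve with
#' distance (the useful region begins there, as for phylogenetic host-use
#' prediction). If the curve already starts on the crossed side the horizon
#' is 0; if it never crosses, the horizon is `+Inf` (for `"falls_below"`
#' this is the fully-deterministic perfect-forecast case; for
#' `"rises_above"` the useful region is never reached).
#'
#' Missing curve points are skipped, never interpolated across. Only the
#' first crossing is reported; later re-crossings are the domain of
#' [detect_blind_spots()].
#'
#' @param curve An [proficiency_curve()].
#' @param threshold Proficiency threshold, within the metric's range.
#' @param crossing `"falls_below"` or `"rises_above"`. When `NULL` the
#'   default follows the metric's orientation: `"falls_below"` for
#'   higher-is-better metrics (usefulness ends when proficiency drops) and
#'   `"rises_above"` for error metrics (usefulness ends when the error
#'   climbs past the tolerance).
#' @param interpolation `"linear"` (crossing placed by linear interpolation
#'   between adjacent points) or `"step"` (crossing placed at the first
#'   observed point on the crossed side).
#'
#' @return An object of class `"eh_horizon"`: list with `horizon`,
#'   `threshold`, `crossing`, `unit`, `metric` and optional `interval`.
#' @examples
#' cv <- proficiency_curve(0:10, seq(1, 0, by = -0.1), "correlation", TRUE)
#' horizon_from_curve(cv, 0.5)$horizon  # 5
#' @export
horizon_from_curve <- function(curve, threshold,
                               crossing = NULL,
                               interpolation = c("linear", "step")) {
  interpolation <- match.arg(interpolation)
  if (!inherits(curve, "eh_curve")) stop("`curve` must be a proficiency_curve")
  if (is.null(crossing))
    crossing <- if (curve$higher_is_better) "falls_below" else "rises_above"
  crossing <- match.arg(crossing, c("falls_below", "rises_above"))
  rng <- metric_range(curve$metric)
  if (threshold < rng[1L] || threshold > rng[2L])
    stop("threshold ", threshold, " outside the range of metric '",
         curve$metric, "'")
  ok <- !is.na(curve$mean_proficiency)
  if (sum(ok) < 2L) stop("curve has fewer than 2 non-missing points")
  d <- curve$distances[ok]
  v <- curve$mean_proficiency[ok]
  h <- first_crossing(d, v, threshold, crossing, interpolation)
  structure(list(horizon = h, threshold = threshold, crossing = crossing,
                 unit = curve$unit, metric = curve$metric, interval = NULL),
            class = "eh_horizon")
}

# Core crossing scan shared by the estimators. `crossing` states the
# direction of the crossing that ends/starts usefulness; the "crossed side"
# is below the threshold for falls_below and above it for rises_above.
first_crossing <- function(d, v, threshold, crossing, interpolation) {
  on_side <- if (crossing == "falls_below") v < threshold else v > threshold
  if (on_side[1L]) return(0)
  for (i in seq_len(length(d) - 1L)) {
    if (on_side[i + 1L]) {
      if (interpolation == "step") return(d[i + 1L])
      return(d[i] + (threshold - v[i]) / (v[i + 1L] - v[i]) *
               (d[i + 1L] - d[i]))
    }
  }
  Inf
}

#' @export
print.eh_horizon <- function(x, ...) {
  cat("Forecast horizon: ", format_dist(x$horizon), " ", x$unit, "s (",
      x$metric, " ", x$crossing, " ", x$threshold, ")\n", sep = "")
  if (!is.null(x$interval))
    cat("  95% interval: [", format_dist(x$interval[1L]), ", ",
        format_dist(x$interval[2L]), "]\n", sep = "")
  invisible(x)
}

format_dist <- function(x) {
  if (is.infinite(x)) "Inf" else format(signif(x, 5))
}

#' Distribution of forecast horizons across replicates
#'
#' Because forecast proficiency at any distance is a distribution across
#' replicate forecasts, so is the forecast horizon. This computes the
#' horizon of every replicate curve and summarises: median, a percentile
#' band, the mean over finite horizons, and the count of infinite horizons.
#' Infinite horizons are ranked above all finite values, so the median is
#' infinite when more than half the replicates never cross.
#'
#' @param curves A list of proficiency curves, or a single curve carrying a
#'   replicate matrix (each row is then treated as one replicate curve).
#' @inheritParams horizon_from_curve
#' @param band Length-2 percentile pair for the summary band. The default is
#'   the interquartile envelope; `c(0.55, 0.65)` gives a deliberately narrow
#'   band for plots with many overlapping series.
#'
#' @return An object of class `"eh_horizon_dist"` with fields `horizons`
#'   (per-replicate values, `Inf` allowed), `median`, `band`, `probs`,
#'   `mean_finite`, `n_infinite`, plus threshold/crossing/unit metadata.
#' @export
horizon_distribution <- function(curves, threshold, crossing = NULL,
                                 band = c(0.25, 0.75),
                                 interpolation = c("linear", "step")) {
  interpolation <- match.arg(interpolation)
  if (inherits(curves, "eh_curve")) curves <- split_replicate_curves(curves)
  if (length(curves) < 2L) stop("at least 2 replicate curves are required")
  ests <- lapply(curves, horizon_from_curve, threshold = threshold,
                 crossing = crossing, interpolation = interpolation)
  h <- vapply(ests, function(e) e$horizon, numeric(1))
  fin <- h[is.finite(h)]
  structure(list(horizons = h,
                 median = percentile_with_inf(h, 0.5),
                 band = percentile_with_inf(h, band),
                 probs = band,
                 mean_finite = if (length(fin)) mean(fin) else NA_real_,
                 n_infinite = sum(is.infinite(h)),
                 threshold = threshold,
                 crossing = ests[[1L]]$crossing,
                 unit = ests[[1L]]$unit,
                 metric = ests[[1L]]$metric),
            class = "eh_horizon_dist")
}

#' @export
print.eh_horizon_dist <- function(x, ...) {
  cat("Horizon distribution over ", length(x$horizons), " replicates (",
      x$metric, " ", x$crossing, " ", x$threshold, ")\n",
      "  median ", format_dist(x$median), " ", x$unit, "s; ",
      100 * x$probs[1L], "-", 100 * x$probs[2L], "th percentiles [",
      format_dist(x$band[1L]), ", ", format_dist(x$band[2L]), "]; ",
      x$n_infinite, " infinite\n", sep = "")
  invisible(x)
}

#' Forecast horizon from a fitted decay curve
#'
#' Fits a parametric decay family to the (distance, proficiency) points by
#' least squares and solves the threshold crossing on the fitted curve,
#' propagating the fit's 95% confidence band (delta method on the fitted
#' values) to a crossing interval: the interval endpoints are where the
#' lower and upper envelope curves cross the threshold. This is the
#' estimator of choice when the empirical curve is sparse or noisy.
#' Crossings are certified only within the observed distance range; a fitted
#' curve that stays above the threshold over the data reports `Inf` rather
#' than an extrapolated crossing.
#'
#' Families: `"exponential"` `a * exp(-d / tau)`; `"logistic"`
#' `a / (1 + exp((d - m) / s))` (a decreasing sigmoid); and
#' `"monotone_spline"`, a monotone Hermite interpolating spline (no
#' parametric form, hence no confidence interval).
#'
#' @param curve An [proficiency_curve()] with at least 4 non-missing points.
#' @param family Decay family, see Details.
#' @param threshold Proficiency threshold.
#' @param conf_level Confidence level for the crossing interval.
#' @return An `"eh_horizon"` whose `interval` element holds the crossing
#'   interval (parametric families only) and with the fit attached as
#'   attribute `"fit"`.
#' @export
fit_decay_curve_horizon <- function(curve,
                                    family = c("exponential", "logistic",
                                               "monotone_spline"),
                                    threshold, conf_level = 0.95) {
  family <- match.arg(family)
  if (!inherits(curve, "eh_curve")) stop("`curve` must be a proficiency_curve")
  ok <- !is.na(curve$mean_proficiency)
  if (sum(ok) < 4L) stop("at least 4 non-missing points are required")
  d <- curve$distances[ok]
  v <- curve$mean_proficiency[ok]

  if (family == "monotone_spline") {
    f <- stats::splinefun(d, v, method = "monoH.FC")
    h <- crossing_of_function(f, range(d), threshold)
    out <- structure(list(horizon = h, threshold = threshold,
                          crossing = "falls_below", unit = curve$unit,
                          metric = curve$metric, interval = NULL),
                     class = "eh_horizon")
    attr(out, "fit") <- f
    return(out)
  }

  dat <- data.frame(d = d, v = v)
  if (family == "exponential") {
    a0 <- max(v[1L], 1e-8)
    pos <- v > 0
    tau0 <- if (sum(pos) >= 2) {
      sl <- unname(stats::coef(stats::lm(log(v[pos]) ~ d[pos]))[2L])
      if (is.finite(sl) && sl < 0) -1 / sl else diff(range(d)) / 2
    } else diff(range(d)) / 2
    fit <- minpack.lm::nlsLM(v ~ a * exp(-d / tau), data = dat,
                             start = list(a = a0, tau = tau0),
                             lower = c(a = 1e-12, tau = 1e-9),
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200))
    pars <- stats::coef(fit)
    pred <- function(dd, p) p[["a"]] * exp(-dd / p[["tau"]])
    grad <- function(dd, p) cbind(exp(-dd / p[["tau"]]),
                                  p[["a"]] * exp(-dd / p[["tau"]]) *
                                    dd / p[["tau"]]^2)
    solve_cross <- function(p) {
      if (threshold <= 0) return(Inf)
      if (p[["a"]] <= threshold) return(0)
      p[["tau"]] * log(p[["a"]] / threshold)
    }
  } else {
    a0 <- max(v)
    m0 <- stats::median(d)
    s0 <- diff(range(d)) / 6
    fit <- minpack.lm::nlsLM(v ~ a / (1 + exp((d - m) / s)), data = dat,
                             start = list(a = a0, m = m0, s = s0),
                             lower = c(a = 1e-12, m = -Inf, s = 1e-9),
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200))
    pars <- stats::coef(fit)
    pred <- function(dd, p) p[["a"]] / (1 + exp((dd - p[["m"]]) / p[["s"]]))
    grad <- function(dd, p) {
      e <- exp((dd - p[["m"]]) / p[["s"]])
      den <- (1 + e)^2
      cbind(1 / (1 + e),
            p[["a"]] * e / (p[["s"]] * den),
            p[["a"]] * e * (dd - p[["m"]]) / (p[["s"]]^2 * den))
    }
    solve_cross <- function(p) {
      if (threshold <= 0) return(Inf)
      ratio <- p[["a"]] / threshold - 1
      if (ratio <= 0) return(0)
      p[["m"]] + p[["s"]] * log(ratio)
    }
  }
  if (!fit$convInfo$isConv && fit$convInfo$stopCode == 0)
    stop("decay-curve fit did not converge: ", fit$convInfo$stopMessage)

  # crossings are only certified within the observed distance range: a
  # fitted curve that stays above the threshold over the data reports an
  # infinite horizon rather than an extrapolated one
  h <- max(0, solve_cross(pars))
  if (h > max(d)) h <- Inf
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  interval <- NULL
  if (!is.null(vc) && all(is.finite(vc))) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    envelope <- function(dd, sign) {
      g <- grad(dd, pars)
      se <- sqrt(pmax(0, rowSums((g %*% vc) * g)))
      pred(dd, pars) + sign * z * se
    }
    span <- range(d)
    lo <- crossing_of_function(function(dd) envelope(dd, -1), span, threshold)
    hi <- crossing_of_function(function(dd) envelope(dd, +1), span, threshold)
    interval <- sort(c(lo, hi))
  }
  out <- structure(list(horizon = h, threshold = threshold,
                        crossing = "falls_below", unit = curve$unit,
                        metric = curve$metric, interval = interval),
                   class = "eh_horizon")
  attr(out, "fit") <- fit
  out
}

# First falls-below crossing of a vectorised function on an interval, by a
# fine grid scan refined with uniroot. Inf when the function stays above.
crossing_of_function <- function(f, span, threshold, n_grid = 4096L) {
  dd <- seq(span[1L], span[2L], length.out = n_grid)
  vv <- f(dd)
  if (vv[1L] < threshold) return(0)
  below <- which(vv < threshold)
  if (!length(below)) return(Inf)
  i <- below[1L]
  stats::uniroot(function(x) f(x) - threshold,
                 lower = dd[i - 1L], upper = dd[i],
                 tol = 1e-12)$root
}

#' Forecast blind spots of a proficiency curve
#'
#' Non-monotonic proficiency curves can dip below the usefulness threshold
#' on an interior interval and recover: a forecast blind spot. This returns
#' the maximal intervals of the curve's support on the requested side of the
#' threshold, with interval endpoints placed by linear interpolation at the
#' crossings. The `"bad"` side is below the threshold for higher-is-better
#' metrics and above it for error metrics; `side = "good"` returns the
#' complementary intervals, so the two calls partition the support exactly.
#'
#' @inheritParams horizon_from_curve
#' @param side `"bad"` (default) or `"good"`.
#' @return A data frame with columns `start` and `end`, zero rows when the
#'   curve never visits the requested side.
#' @export
detect_blind_spots <- function(curve, threshold, side = c("bad", "good")) {
  side <- match.arg(side)
  if (!inherits(curve, "eh_curve")) stop("`curve` must be a proficiency_curve")
  ok <- !is.na(curve$mean_proficiency)
  if (sum(ok) < 2L) stop("curve has fewer than 2 non-missing points")
  d <- curve$distances[ok]
  v <- curve$mean_proficiency[ok]
  bad <- if (curve$higher_is_better) v < threshold else v > threshold
  if (side == "good") bad <- !bad
  starts <- c(); ends <- c()
  open <- NA_real_
  if (bad[1L]) open <- d[1L]
  for (i in seq_len(length(d) - 1L)) {
    if (bad[i] == bad[i + 1L]) next
    cx <- d[i] + (threshold - v[i]) / (v[i + 1L] - v[i]) * (d[i + 1L] - d[i])
    if (bad[i + 1L]) {
      open <- cx
    } else {
      starts <- c(starts, open); ends <- c(ends, cx); open <- NA_real_
    }
  }
  if (!is.na(open)) {
    starts <- c(starts, open); ends <- c(ends, d[length(d)])
  }
  data.frame(start = starts %||% numeric(0), end = ends %||% numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
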