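#' Construct a proficiency curve
#'
#' A proficiency curve records forecast proficiency as a function of forecast
#' distance (generations, days, km, or millions of years of phylogenetic
#' distance). It is the common currency of the package: every pipeline ends
#' in a proficiency curve, and every horizon estimator starts from one.
#'
#' @param distances Strictly increasing numeric vector of forecast distances.
#' @param mean_proficiency Numeric vector of mean proficiency per distance;
#'   `NA` marks distances where the metric is undefined (e.g. a zero-variance
#'   window).
#' @param metric Name of the proficiency measure (e.g. `"correlation"`,
#'   `"r_squared"`, `"MSE"`, `"auc"`, `"sorensen"`).
#' @param higher_is_better Logical flag giving the metric's orientation.
#' @param unit Distance unit, one of `"generation"`, `"day"`, `"km"`, `"MYA"`,
#'   `"arbitrary"`.
#' @param replicates Optional matrix (replicates x distances) of per-replicate
#'   proficiency values; when present, `mean_proficiency` must equal its
#'   per-distance mean (computed over non-missing replicates).
#' @param band Optional list with elements `lower`, `upper` (vectors along
#'   `distances`) and `probs` (the two percentile levels).
#'
#' @return An object of class `"eh_curve"`.
#' @export
proficiency_curve <- function(distances, mean_proficiency, metric,
                              higher_is_better,
                              unit = c("generation", "day", "km", "MYA",
                                       "arbitrary"),
                              replicates = NULL, band = NULL) {
  unit <- match.arg(unit)
  distances <- as.numeric(distances)
  mean_proficiency <- as.numeric(mean_proficiency)
  if (length(distances) != length(mean_proficiency))
    stop("`distances` and `mean_proficiency` must have equal length")
  if (any(diff(distances) <= 0))
    stop("`distances` must be strictly increasing")
  rng <- metric_range(metric)
  ok <- !is.na(mean_proficiency)
  if (any(mean_proficiency[ok] < rng[1L] - 1e-9 |
          mean_proficiency[ok] > rng[2L] + 1e-9))
    stop("proficiency values outside the range of metric '", metric, "'")
  if (!is.null(replicates)) {
    replicates <- as.matrix(replicates)
    if (ncol(replicates) != length(distances))
      stop("`replicates` must have one column per distance")
    m <- colMeans(replicates, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    if (any(abs(m - mean_proficiency) > 1e-8, na.rm = TRUE))
      stop("`mean_proficiency` does not match the replicate means")
  }
  if (!is.null(band)) {
    stopifnot(is.list(band), length(band$lower) == length(distances),
              length(band$upper) == length(distances))
  }
  structure(list(distances = distances,
                 mean_proficiency = mean_proficiency,
                 metric = metric,
                 higher_is_better = isTRUE(higher_is_better),
                 unit = unit,
                 replicates = replicates,
                 band = band),
            class = "eh_curve")
}

#' @export
print.eh_curve <- function(x, ...) {
  cat("Proficiency curve [", x$metric, ", ",
      if (x$higher_is_better) "higher is better" else "lower is better",
      "]\n  ", length(x$distances), " distances over [",
      signif(x$distances[1L], 4), ", ",
      signif(x$distances[length(x$distances)], 4), "] ", x$unit,
      if (!is.null(x$replicates)) paste0("; ", nrow(x$replicates),
                                         " replicates"),
      "\n", sep = "")
  invisible(x)
}

# Theoretical range of a named metric; error metrics are [0, Inf) except
# bias which is signed.
metric_range <- function(metric) {
  switch(metric,
         correlation = , sqrt_pearson = c(-1, 1),
         r_squared = , auc = , sorensen = c(0, 1),
         bias = c(-Inf, Inf),
         MSE = , RMSE = , MAE = c(0, Inf),
         c(-Inf, Inf))
}

# Sliding-window index sets over a time axis of length n.
window_starts <- function(n, window_length, step) {
  if (window_length < 3L) stop("`window_length` must be at least 3")
  if (window_length > n) stop("`window_length` exceeds the trajectory length")
  if (step < 1L) stop("`step` must be at least 1")
  seq.int(1L, n - window_length + 1L, by = step)
}

# Pearson correlation returning NA (not an error, not zero) for windows in
# which either series is constant: the metric is undefined there and the
# missing value must propagate into the curve.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Windowed-correlation proficiency curve
#'
#' Slides a window along the shared time axis of truth and forecasts and
#' computes, per window and per forecast replicate, the Pearson correlation
#' between true and forecast values. The distance assigned to a window is its
#' centre (the mean of the window's time points), so the curve reads as
#' proficiency at a given forecast lead time.
#'
#' Windows in which either series has zero variance yield `NA`; missing
#' values propagate into the curve and are skipped (never imputed) by the
#' horizon estimators.
#'
#' @param ensemble A [forecast_ensemble()].
#' @param window_length Number of time points per window (>= 3).
#' @param step Window stride in time points.
#'
#' @return An [proficiency_curve()] with `metric = "correlation"`,
#'   `higher_is_better = TRUE`, and the per-replicate matrix retained.
#' @examples
#' tru <- trajectory(1:30, sin(1:30))
#' ens <- forecast_ensemble(tru, tru)
#' cv <- windowed_correlation_curve(ens, window_length = 5)
#' all(cv$mean_proficiency == 1)
#' @export
windowed_correlation_curve <- function(ensemble, window_length = 10L,
                                       step = 1L) {
  windowed_metric_curve(ensemble, window_length, step,
                        fun = safe_cor,
                        metric = "correlation", higher_is_better = TRUE)
}

#' Windowed error-metric proficiency curve
#'
#' As [windowed_correlation_curve()], but computes an error measure on the
#' residuals (forecast minus truth) within each window: mean error
#' (`"bias"`), mean square error (`"MSE"`), its root (`"RMSE"`), or mean
#' absolute error (`"MAE"`). Lower values indicate better forecasts.
#'
#' @inheritParams windowed_correlation_curve
#' @param metric One of `"bias"`, `"MSE"`, `"RMSE"`, `"MAE"`.
#' @return An [proficiency_curve()] with `higher_is_better = FALSE`.
#' @export
error_metric_curve <- function(ensemble,
                               metric = c("bias", "MSE", "RMSE", "MAE"),
                               window_length = 10L, step = 1L) {
  metric <- match.arg(metric)
  fun <- switch(metric,
                bias = function(t, f) mean(f - t),
                MSE = function(t, f) mean((f - t)^2),
                RMSE = function(t, f) sqrt(mean((f - t)^2)),
                MAE = function(t, f) mean(abs(f - t)))
  windowed_metric_curve(ensemble, window_length, step, fun = function(x, y) {
    fun(x, y)
  }, metric = metric, higher_is_better = FALSE)
}

#' Windowed R-squared proficiency curve
#'
#' Computes R-squared between truth and forecast within each window. The
#' default convention is the squared Pearson correlation of observed versus
#' predicted values; `convention = "ss"` instead uses
#' 1 - SS_res / SS_tot (which additionally penalises bias and can go
#' negative; negative values are truncated at 0 so the curve stays on the
#' documented \[0, 1\] scale).
#'
#' @inheritParams windowed_correlation_curve
#' @param convention `"squared_correlation"` (default) or `"ss"`.
#' @return An [proficiency_curve()] with `metric = "r_squared"`.
#' @export
r_squared_curve <- function(ensemble, window_length = 10L, step = 1L,
                            convention = c("squared_correlation", "ss")) {
  convention <- match.arg(convention)
  fun <- if (convention == "squared_correlation") {
    function(t, f) {
      r <- safe_cor(t, f)
      if (is.na(r)) NA_real_ else r^2
    }
  } else {
    function(t, f) {
      sst <- sum((t - mean(t))^2)
      if (sst == 0) return(NA_real_)
      max(0, 1 - sum((f - t)^2) / sst)
    }
  }
  windowed_metric_curve(ensemble, window_length, step, fun = fun,
                        metric = "r_squared", higher_is_better = TRUE)
}

# Shared engine: apply fun(truth_window, forecast_window) over all windows
# and replicates.
windowed_metric_curve <- function(ensemble, window_length, step, fun,
                                  metric, higher_is_better) {
  if (!inherits(ensemble, "eh_ensemble"))
    stop("`ensemble` must be a forecast_ensemble")
  tru <- ensemble$truth
  n <- length(tru$times)
  starts <- window_starts(n, as.integer(window_length), as.integer(step))
  nrep <- length(ensemble$forecasts)
  vals <- matrix(NA_real_, nrow = nrep, ncol = length(starts))
  centres <- vapply(starts, function(s) {
    mean(tru$times[s:(s + window_length - 1L)])
  }, numeric(1))
  for (r in seq_len(nrep)) {
    fv <- ensemble$forecasts[[r]]$values
    for (k in seq_along(starts)) {
      idx <- starts[k]:(starts[k] + window_length - 1L)
      vals[r, k] <- fun(tru$values[idx], fv[idx])
    }
  }
  m <- colMeans(vals, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  unit <- if (tru$unit %in% c("generation", "day")) tru$unit else "arbitrary"
  proficiency_curve(centres, m, metric = metric,
                    higher_is_better = higher_is_better, unit = unit,
                    replicates = vals)
}

# Percentile of a sample by linear interpolation between order statistics
# (quantile type 7), with infinities ranked above all finite values. When an
# interpolation bracket touches an infinite order statistic the percentile is
# infinite.
percentile_with_inf <- function(x, p) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  s <- sort(x)                      # Inf sorts last
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    a <- s[lo]; b <- s[hi]
    if (is.infinite(a) || (is.infinite(b) && h > lo)) return(Inf)
    a + (h - lo) * (b - a)
  }, numeric(1))
}

#' Aggregate replicate proficiency curves
#'
#' Combines curves measured on the same distance axis (e.g. one per forecast
#' replicate) into a single curve whose mean is the per-distance arithmetic
#' mean and whose band holds interpolation-based percentile envelopes.
#'
#' @param curves A list of [proficiency_curve()] objects sharing distances,
#'   metric and orientation, or a single curve carrying a replicate matrix.
#' @param band Length-2 numeric vector of percentile levels in \[0, 1\]
#'   (default the interquartile envelope).
#' @return An [proficiency_curve()] with the replicate matrix retained.
#' @export
aggregate_curves <- function(curves, band = c(0.25, 0.75)) {
  if (inherits(curves, "eh_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1L, length(band) == 2L, band[1L] <= band[2L])
  ref <- curves[[1L]]
  rows <- list()
  for (cu in curves) {
    if (!inherits(cu, "eh_curve")) stop("all elements must be curves")
    if (length(cu$distances) != length(ref$distances) ||
        any(cu$distances != ref$distances))
      stop("curves do not share a distance axis")
    if (cu$metric != ref$metric ||
        cu$higher_is_better != ref$higher_is_better)
      stop("curves do not share metric/orientation")
    rows[[length(rows) + 1L]] <- if (is.null(cu$replicates))
      matrix(cu$mean_proficiency, nrow = 1L) else cu$replicates
  }
  reps <- do.call(rbind, rows)
  m <- colMeans(reps, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  lower <- apply(reps, 2L, percentile_with_inf, p = band[1L])
  upper <- apply(reps, 2L, percentile_with_inf, p = band[2L])
  proficiency_curve(ref$distances, m, metric = ref$metric,
                    higher_is_better = ref$higher_is_better, unit = ref$unit,
                    replicates = reps,
                    band = list(lower = lower, upper = upper, probs = band))
}

# Split a curve's replicate matrix into one single-replicate curve per row.
split_replicate_curves <- function(curve) {
  if (is.null(curve$replicates)) return(list(curve))
  lapply(seq_len(nrow(curve$replicates)), function(i) {
    v <- curve$replicates[i, ]
    proficiency_curve(curve$distances, v, metric = curve$metric,
                      higher_is_better = curve$higher_is_better,
                      unit = curve$unit)
  })
}
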