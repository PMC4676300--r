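#' Create a trajectory
#'
#' A trajectory is a time-ordered series of a single state variable
#' (abundance, biomass, or any other forecastable quantity), possibly one of
#' many stochastic replicates of the same process.
#'
#' @param times Numeric vector of strictly increasing observation times.
#' @param values Numeric vector of the same length as `times`. Population
#'   variables are expected to be non-negative, but this is not enforced so
#'   that derived quantities (anomalies, residuals) can be carried too.
#' @param unit Unit label for the time axis, one of `"generation"`, `"day"`
#'   or `"arbitrary"`.
#' @param label Free-text label identifying the series.
#'
#' @return An object of class `"eh_trajectory"`: a list with elements
#'   `times`, `values`, `unit` and `label`.
#' @examples
#' tr <- trajectory(0:9, runif(10), unit = "generation")
#' length(tr$values)
#' @export
trajectory <- function(times, values, unit = c("generation", "day", "arbitrary"),
                       label = "") {
  unit <- match.arg(unit)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length")
  if (length(times) < 2L)
    stop("a trajectory needs at least 2 points")
  if (anyNA(times) || any(!is.finite(times)))
    stop("`times` must be finite and non-missing")
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  structure(list(times = times, values = values, unit = unit,
                 label = as.character(label)[1L]),
            class = "eh_trajectory")
}

#' @export
print.eh_trajectory <- function(x, ...) {
  cat("Trajectory", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      "\n  ", length(x$times), " points over [",
      x$times[1L], ", ", x$times[length(x$times)], "] ", x$unit, "s\n",
      sep = "")
  invisible(x)
}

#' Bundle a true trajectory with one or more forecasts
#'
#' All forecast replicates must share the truth's time axis exactly; forecast
#' proficiency is only defined for paired observations at identical times.
#'
#' @param truth An [trajectory()] object: the series taken as the truth.
#' @param forecasts A single trajectory or a list of trajectories, each a
#'   forecast replicate on the same time axis as `truth`.
#'
#' @return An object of class `"eh_ensemble"` with elements `truth` and
#'   `forecasts` (always a list).
#' @examples
#' tru <- trajectory(1:20, rnorm(20))
#' fc <- trajectory(1:20, rnorm(20))
#' ens <- forecast_ensemble(tru, fc)
#' @export
forecast_ensemble <- function(truth, forecasts) {
  if (!inherits(truth, "eh_trajectory"))
    stop("`truth` must be a trajectory")
  if (inherits(forecasts, "eh_trajectory")) forecasts <- list(forecasts)
  if (!is.list(forecasts) || length(forecasts) < 1L)
    stop("at least one forecast is required")
  for (i in seq_along(forecasts)) {
    f <- forecasts[[i]]
    if (!inherits(f, "eh_trajectory"))
      stop("forecast ", i, " is not a trajectory")
    if (length(f$times) != length(truth$times) ||
        any(f$times != truth$times))
      stop("forecast ", i, " does not share the truth's time axis")
  }
  structure(list(truth = truth, forecasts = forecasts),
            class = "eh_ensemble")
}

#' @export
print.eh_ensemble <- function(x, ...) {
  cat("Forecast ensemble: ", length(x$forecasts), " forecast(s), ",
      length(x$truth$times), " time points (", x$truth$unit, "s)\n", sep = "")
  invisible(x)
}
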