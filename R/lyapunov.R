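#' One-dimensional map specification
#'
#' Deterministic one-dimensional maps for twin-trajectory divergence
#' analysis. Built-in families are the logistic map
#' `x' = r x (1 - x)` on (0, 1) and the (rescaled, K = 1) Ricker map
#' `x' = x exp(r (1 - x))` on (0, Inf); a user-supplied update rule can be
#' given as a function (with an optional analytic derivative, required by
#' [le_orbit_average()]).
#'
#' @param family `"logistic"`, `"ricker"` or `"custom"`.
#' @param param Map parameter (the growth rate `r` for the built-ins).
#' @param f,fprime For `family = "custom"`: the update rule and (optionally)
#'   its derivative, each a function of the state.
#' @param domain Length-2 numeric state domain (defaults per family).
#' @return An object of class `"eh_map"`.
#' @examples
#' m <- map_spec("logistic", 3.6)
#' m$f(0.3)
#' @export
map_spec <- function(family = c("logistic", "ricker", "custom"), param = NA,
                     f = NULL, fprime = NULL, domain = NULL) {
  family <- match.arg(family)
  if (family == "logistic") {
    r <- param
    f <- function(x) r * x * (1 - x)
    fprime <- function(x) r * (1 - 2 * x)
    domain <- domain %||% c(0, 1)
  } else if (family == "ricker") {
    r <- param
    f <- function(x) x * exp(r * (1 - x))
    fprime <- function(x) exp(r * (1 - x)) * (1 - r * x)
    domain <- domain %||% c(0, Inf)
  } else {
    if (!is.function(f)) stop("custom maps need an update function `f`")
    domain <- domain %||% c(-Inf, Inf)
  }
  structure(list(family = family, param = param, f = f, fprime = fprime,
                 domain = domain),
            class = "eh_map")
}

iterate_map <- function(map, x0, steps) {
  x <- numeric(steps + 1L)
  x[1L] <- x0
  for (t in seq_len(steps)) {
    xn <- map$f(x[t])
    if (!is.finite(xn) || xn < map$domain[1L] || xn > map$domain[2L])
      stop("trajectory left the domain at step ", t)
    x[t + 1L] <- xn
  }
  x
}

#' Twin-trajectory divergence
#'
#' Iterates two deterministic trajectories from nearby initial conditions
#' `x0` and `x0 + delta0` and records the natural log of their separation
#' `ln |delta_t|` per step. On a chaotic map the early part of this series
#' grows linearly with slope equal to the largest Lyapunov exponent, until
#' the separation saturates at the attractor's diameter.
#'
#' @param map An [map_spec()].
#' @param x0 Initial state (both `x0` and `x0 + delta0` must lie in the
#'   map's domain).
#' @param delta0 Initial separation, > 0 and small relative to the domain.
#' @param steps Number of iterations.
#' @return An object of class `"eh_divergence"`: list with `times`
#'   (0..steps, truncated if the separation underflows to 0),
#'   `log_separation`, `delta0`, and `state_range` (the sampled range of the
#'   twin trajectories, used for saturation detection).
#' @export
twin_divergence <- function(map, x0, delta0, steps = 60L) {
  if (!inherits(map, "eh_map")) stop("`map` must be a map_spec")
  if (!is.numeric(delta0) || delta0 <= 0)
    stop("`delta0` must be strictly positive")
  for (x in c(x0, x0 + delta0))
    if (x < map$domain[1L] || x > map$domain[2L])
      stop("initial condition outside the map's domain")
  xa <- iterate_map(map, x0, steps)
  xb <- iterate_map(map, x0 + delta0, steps)
  sep <- abs(xb - xa)
  keep <- if (any(sep == 0)) seq_len(which(sep == 0)[1L] - 1L)
          else seq_along(sep)
  structure(list(times = (seq_along(sep) - 1L)[keep],
                 log_separation = log(sep[keep]),
                 delta0 = delta0,
                 state_range = diff(range(c(xa, xb)))),
            class = "eh_divergence")
}

#' Largest Lyapunov exponent from a divergence series
#'
#' Least-squares slope of `ln |delta_t|` against time over the
#' pre-saturation range. Exponential growth of the separation only holds
#' while the separation is small compared to the attractor, so the fit range
#' ends at the first step where the separation exceeds 25% of the sampled
#' attractor range (or, when the series carries no state range, 25% of the
#' maximum observed separation).
#'
#' @param div An `"eh_divergence"` from [twin_divergence()], or any list
#'   with `times` and `log_separation`.
#' @return An object of class `"eh_lyapunov"`: list with `lambda` (per time
#'   step), `fit_range` (time indices used), `se` and `r_squared` of the
#'   slope fit.
#' @export
estimate_le <- function(div) {
  t <- div$times
  ls <- div$log_separation
  if (is.null(t) || is.null(ls)) stop("`div` must carry times/log_separation")
  diam <- div$state_range %||% exp(max(ls))
  sat <- exp(ls) > 0.25 * diam
  cut <- if (any(sat)) which(sat)[1L] - 1L else length(t)
  if (cut < 5L) stop("fewer than 5 usable points before saturation")
  tt <- t[seq_len(cut)]
  ll <- ls[seq_len(cut)]
  fit <- stats::lm(ll ~ tt)
  # exact synthetic lines trigger the "perfect fit" note; harmless here
  sm <- suppressWarnings(summary(fit))
  structure(list(lambda = unname(stats::coef(fit)[2L]),
                 fit_range = range(tt),
                 se = sm$coefficients[2L, 2L],
                 r_squared = sm$r.squared),
            class = "eh_lyapunov")
}

#' @export
print.eh_lyapunov <- function(x, ...) {
  cat("Lyapunov exponent estimate: lambda = ", signif(x$lambda, 4),
      " per step (fit over t in [", x$fit_range[1L], ", ", x$fit_range[2L],
      "], R^2 = ", signif(x$r_squared, 3), ")\n", sep = "")
  invisible(x)
}

#' Orbit-average Lyapunov exponent
#'
#' Independent route to the largest Lyapunov exponent of a one-dimensional
#' map: the time average of `ln |f'(x_t)|` along the orbit after a burn-in.
#' Points where the derivative is exactly zero are skipped (they contribute
#' `-Inf` formally; the skip count is recorded in attribute `"n_skipped"`).
#'
#' @param map An [map_spec()] with an analytic derivative.
#' @param x0 Initial state.
#' @param n Number of orbit points averaged (>= 1000).
#' @param burn_in Iterations discarded before averaging.
#' @return The Lyapunov exponent (numeric scalar).
#' @export
le_orbit_average <- function(map, x0, n = 1e5, burn_in = 1000L) {
  if (!inherits(map, "eh_map")) stop("`map` must be a map_spec")
  if (is.null(map$fprime)) stop("the map has no analytic derivative")
  if (n < 1000) stop("`n` must be at least 1000")
  x <- x0
  for (t in seq_len(burn_in)) x <- map$f(x)
  s <- 0; skipped <- 0L
  for (t in seq_len(n)) {
    dfx <- map$fprime(x)
    if (dfx == 0) skipped <- skipped + 1L else s <- s + log(abs(dfx))
    x <- map$f(x)
    if (!is.finite(x)) stop("orbit diverged at step ", t)
  }
  out <- s / (n - skipped)
  if (skipped > 0L) attr(out, "n_skipped") <- skipped
  out
}

#' Predictability time from a Lyapunov exponent
#'
#' Converts the largest Lyapunov exponent into an analytic forecast horizon:
#' with initial-condition uncertainty `delta0` and required forecast
#' precision `Delta`, the time at which the initial error grows too large
#' for a useful forecast is `T_p = (1 / lambda) * ln(Delta / delta0)` for
#' `lambda > 0`. A non-positive exponent means nearby trajectories do not
#' separate, giving an infinite horizon. `T_p` depends on the uncertainties
#' only logarithmically: halving `delta0` buys exactly `ln(2) / lambda`
#' extra time.
#'
#' @param lambda Largest Lyapunov exponent (per time step).
#' @param delta0 Initial-condition uncertainty, with `0 < delta0 <= Delta`.
#' @param Delta Required precision (the proficiency threshold expressed in
#'   state units).
#' @return The predictability time (possibly `Inf`).
#' @examples
#' horizon_from_le(log(2), 1e-5, 1e-1)  # ln(1e4)/ln 2
#' @export
horizon_from_le <- function(lambda, delta0, Delta) {
  if (!(delta0 > 0)) stop("`delta0` must be > 0")
  if (delta0 > Delta)
    stop("`delta0` exceeds `Delta`: the demanded precision is finer than ",
         "the initial uncertainty")
  if (lambda <= 0) return(Inf)
  log(Delta / delta0) / lambda
}
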