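#' Ricker simulation configuration
#'
#' Parameters for Ricker population dynamics
#' `N_{t+1} = N_t exp(r (1 - N_t / K_t))` with a carrying capacity that can
#' change over time. In the default (`k_mode = "linear"`) reading, `K_step`
#' is a per-generation rate of change, `K_t = K0 + K_step * t`; the
#' alternative `"step"` mode holds `K` at `K0` for the first half of the run
#' and at `K0 + K_step` thereafter. With `demographic_stochasticity` the
#' population is integer-valued: each generation's abundance is a Poisson
#' draw with the deterministic expectation as its mean, making `N = 0`
#' absorbing.
#'
#' @param r Intrinsic growth rate per generation (`r = 3` is well inside the
#'   chaotic regime).
#' @param N0 Initial population size (>= 0).
#' @param K0 Initial carrying capacity (> 0).
#' @param K_step Change in carrying capacity per generation (any sign).
#' @param steps Number of generations to simulate (>= 1).
#' @param demographic_stochasticity Logical; Poisson-sample each generation.
#' @param seed Optional integer seed used by the stochastic path; `NULL`
#'   draws from the current RNG stream.
#' @param k_mode `"linear"` or `"step"`, see Description.
#' @return An object of class `"eh_ricker_config"`.
#' @export
ricker_config <- function(r = 3, N0 = 50, K0 = 100, K_step = 0, steps = 100L,
                          demographic_stochasticity = FALSE, seed = NULL,
                          k_mode = c("linear", "step")) {
  k_mode <- match.arg(k_mode)
  stopifnot(steps >= 1, N0 >= 0, K0 > 0)
  tt <- 0:steps
  K <- if (k_mode == "linear") K0 + K_step * tt
       else ifelse(tt < steps / 2, K0, K0 + K_step)
  if (any(K <= 0))
    stop("carrying capacity becomes non-positive over the simulated range")
  structure(list(r = r, N0 = N0, K0 = K0, K_step = K_step,
                 steps = as.integer(steps),
                 demographic_stochasticity = isTRUE(demographic_stochasticity),
                 seed = seed, k_mode = k_mode),
            class = "eh_ricker_config")
}

carrying_capacity <- function(config, t) {
  if (config$k_mode == "linear") config$K0 + config$K_step * t
  else ifelse(t < config$steps / 2, config$K0, config$K0 + config$K_step)
}

#' Simulate Ricker population dynamics
#'
#' @param config An [ricker_config()].
#' @return An [trajectory()] over generations `0..steps`. Integer-valued
#'   when demographic stochasticity is on.
#' @examples
#' tr <- simulate_ricker(ricker_config(r = 3, steps = 50))
#' range(tr$values)
#' @export
simulate_ricker <- function(config) {
  stopifnot(inherits(config, "eh_ricker_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- numeric(config$steps + 1L)
  N[1L] <- if (config$demographic_stochasticity) round(config$N0) else config$N0
  for (t in seq_len(config$steps)) {
    Kt <- carrying_capacity(config, t - 1)
    mu <- N[t] * exp(config$r * (1 - N[t] / Kt))
    if (!is.finite(mu))
      stop("population size overflowed at generation ", t)
    N[t + 1L] <- if (config$demographic_stochasticity) {
      if (N[t] == 0) 0 else stats::rpois(1L, mu)
    } else mu
  }
  trajectory(0:config$steps, N, unit = "generation", label = "ricker")
}

#' Parameter-uncertainty specification
#'
#' Coefficients of variation describing how uncertain the forecaster is
#' about the true growth rate, initial population size and rate of change
#' of carrying capacity. Uncertain quantities are drawn from a normal
#' distribution centred on the true value with SD = CV * true value;
#' quantities that must stay positive (`r`, `N0`) are truncated at zero by
#' resampling.
#'
#' @param cv_r,cv_N0,cv_Kstep Coefficients of variation (>= 0).
#' @param distribution Currently only `"truncated_normal"`.
#' @return An object of class `"eh_uncertainty"`.
#' @export
uncertainty_spec <- function(cv_r = 0, cv_N0 = 0, cv_Kstep = 0,
                             distribution = "truncated_normal") {
  stopifnot(cv_r >= 0, cv_N0 >= 0, cv_Kstep >= 0,
            distribution == "truncated_normal")
  structure(list(cv_r = cv_r, cv_N0 = cv_N0, cv_Kstep = cv_Kstep,
                 distribution = distribution),
            class = "eh_uncertainty")
}

rtruncnorm_pos <- function(mean, sd, max_tries = 1000L) {
  if (sd == 0) return(mean)
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1L, mean, sd)
    if (x > 0) return(x)
  }
  stop("resampling cap exceeded while truncating at zero")
}

#' Draw a predictor configuration around the truth
#'
#' Replaces each uncertain quantity of the true configuration with a random
#' draw per [uncertainty_spec()]. `r` and `N0` are truncated at zero;
#' `K_step` may change sign. The predictor is always deterministic:
#' demographic stochasticity is a property of the true dynamics only, so the
#' flag is dropped from the sampled configuration.
#'
#' @param truth An [ricker_config()].
#' @param u An [uncertainty_spec()].
#' @return An [ricker_config()] with attribute `"draws"` holding the drawn
#'   values.
#' @export
sample_predictor_config <- function(truth, u) {
  stopifnot(inherits(truth, "eh_ricker_config"),
            inherits(u, "eh_uncertainty"))
  r <- rtruncnorm_pos(truth$r, u$cv_r * abs(truth$r))
  N0 <- rtruncnorm_pos(truth$N0, u$cv_N0 * abs(truth$N0))
  cfg <- NULL
  for (i in seq_len(1000L)) {
    Ks <- if (u$cv_Kstep == 0 || truth$K_step == 0) truth$K_step
          else stats::rnorm(1L, truth$K_step, u$cv_Kstep * abs(truth$K_step))
    # K must stay positive over the whole run; resample K_step otherwise
    cfg <- tryCatch(
      ricker_config(r = r, N0 = N0, K0 = truth$K0, K_step = Ks,
                    steps = truth$steps,
                    demographic_stochasticity = FALSE, seed = NULL,
                    k_mode = truth$k_mode),
      error = function(e) NULL)
    if (!is.null(cfg)) break
  }
  if (is.null(cfg)) stop("resampling cap exceeded for K_step")
  attr(cfg, "draws") <- c(r = r, N0 = N0, K_step = Ks)
  cfg
}

#' Ricker forecast-horizon experiment
#'
#' The full case-study pipeline: simulate true dynamics, draw `n_reps`
#' predictor parameterisations from the uncertainty specification, simulate
#' each (deterministic) forecast, measure windowed-correlation forecast
#' proficiency against the truth, and summarise the forecast horizon both on
#' the mean proficiency curve and as a distribution of per-replicate
#' horizons.
#'
#' When the truth is stochastic it is re-simulated for every replicate by
#' default (`resimulate_truth = FALSE` holds one realisation fixed instead);
#' a deterministic truth is simulated once.
#'
#' @param truth An [ricker_config()] describing the true dynamics.
#' @param u An [uncertainty_spec()].
#' @param n_reps Number of forecast replicates (>= 2).
#' @param window,step Window length and stride for the proficiency curve.
#' @param threshold Forecast proficiency threshold (correlation scale).
#' @param horizon_mode `"per_replicate"` (a horizon per replicate curve,
#'   summarised as a distribution) or `"mean_curve"` (one horizon of the
#'   replicate-averaged curve); both are always computed, the flag selects
#'   which one `$horizon` points to.
#' @param band Percentile pair for curve and horizon summaries.
#' @param seed Integer seed making the whole experiment reproducible.
#' @param resimulate_truth Re-simulate a stochastic truth per replicate.
#' @return An object of class `"eh_ricker_experiment"`: list with `curve`
#'   (aggregated proficiency curve with replicates and band),
#'   `horizon_dist`, `mean_curve_horizon`, `horizon` (per `horizon_mode`),
#'   `draws` (data frame of sampled parameters), `truth_config`, `seed`.
#' @export
run_ricker_experiment <- function(truth, u, n_reps = 200L, window = 10L,
                                  step = 1L, threshold = 0.5,
                                  horizon_mode = c("per_replicate",
                                                   "mean_curve"),
                                  band = c(0.25, 0.75), seed = 1L,
                                  resimulate_truth = TRUE) {
  horizon_mode <- match.arg(horizon_mode)
  stopifnot(inherits(truth, "eh_ricker_config"), n_reps >= 2)
  set.seed(seed)
  truth_fixed <- if (!truth$demographic_stochasticity || !resimulate_truth)
    simulate_ricker(truth) else NULL
  curves <- vector("list", n_reps)
  draws <- matrix(NA_real_, n_reps, 3L,
                  dimnames = list(NULL, c("r", "N0", "K_step")))
  for (i in seq_len(n_reps)) {
    tru_traj <- truth_fixed %||% simulate_ricker(truth)
    pred_cfg <- sample_predictor_config(truth, u)
    draws[i, ] <- attr(pred_cfg, "draws")
    fc <- simulate_ricker(pred_cfg)
    ens <- forecast_ensemble(tru_traj, fc)
    curves[[i]] <- windowed_correlation_curve(ens, window_length = window,
                                              step = step)
  }
  curve <- aggregate_curves(curves, band = band)
  hd <- horizon_distribution(curve, threshold = threshold,
                             crossing = "falls_below", band = band)
  mh <- horizon_from_curve(curve, threshold = threshold,
                           crossing = "falls_below")
  structure(list(curve = curve,
                 horizon_dist = hd,
                 mean_curve_horizon = mh,
                 horizon = if (horizon_mode == "per_replicate") hd$median
                           else mh$horizon,
                 horizon_mode = horizon_mode,
                 draws = as.data.frame(draws),
                 truth_config = truth, uncertainty = u,
                 threshold = threshold, seed = seed),
            class = "eh_ricker_experiment")
}

#' @export
print.eh_ricker_experiment <- function(x, ...) {
  cat("Ricker forecast-horizon experiment (", nrow(x$draws),
      " replicates, threshold ", x$threshold, ")\n", sep = "")
  print(x$horizon_dist)
  cat("  mean-curve horizon: ", format_dist(x$mean_curve_horizon$horizon),
      " generations\n", sep = "")
  invisible(x)
}
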