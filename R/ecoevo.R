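#' Eco-evolutionary community configuration
#'
#' A community of competitors on a one-dimensional resource axis, in the
#' standard Gaussian-kernel trait-based competition formulation. Species `i`
#' carries a trait `x_i` (its resource-use optimum). The resource
#' distribution gives a trait-dependent carrying capacity
#' `K_i(t) = K_max exp(kappa * theta_t - (x_i - theta_t)^2 / (2 sigma_K^2))`
#' around the time-varying resource optimum `theta_t`; the environmental
#' state moves both the position of the resource distribution and (through
#' the log-linear productivity coupling `kappa = env_K_coupling`) its
#' height, so good years carry more total resource. Competition between
#' species declines with trait distance,
#' `alpha_ij = exp(-(x_i - x_j)^2 / (2 sigma_alpha^2))`, and abundances
#' follow the discrete-time (Ricker-form) Lotka-Volterra update
#' `N_i(t+1) = N_i(t) exp(r_max (1 - sum_j alpha_ij N_j / K_i(t)))`.
#' With evolution enabled, traits ascend the per-capita growth gradient
#' at rate `h`: `x_i(t+1) = x_i(t) + h * d g_i / d x_i` evaluated at the
#' current state.
#'
#' @param n_species Number of species (>= 2).
#' @param traits Initial trait values (default equally spaced on \[-2, 2\]).
#' @param N0 Initial abundances (> 0; scalar recycled).
#' @param r_max Per-generation maximal growth rate.
#' @param K_max Carrying-capacity peak (abundance units).
#' @param sigma_K Resource-distribution width (trait units).
#' @param sigma_alpha Competition-kernel width (trait units).
#' @param h Evolution rate (>= 0; 0 disables trait change).
#' @param env_K_coupling Log-linear response of resource productivity to the
#'   environmental state (`kappa` above; 0 makes the environment move the
#'   resource optimum only).
#' @param extinction_threshold Abundance below which a species is set to 0
#'   (and stays there).
#' @param steps Number of generations.
#' @return An object of class `"eh_ecoevo_config"`.
#' @export
ecoevo_config <- function(n_species = 10L,
                          traits = seq(-2, 2, length.out = n_species),
                          N0 = 10, r_max = 1, K_max = 100, sigma_K = 1,
                          sigma_alpha = 0.5, h = 0, env_K_coupling = 1.5,
                          extinction_threshold = 1e-6 * K_max,
                          steps = 500L) {
  stopifnot(n_species >= 2, length(traits) == n_species,
            sigma_K > 0, sigma_alpha > 0, h >= 0, steps >= 1,
            all(N0 > 0))
  N0 <- rep_len(N0, n_species)
  structure(list(n_species = as.integer(n_species), traits = as.numeric(traits),
                 N0 = N0, r_max = r_max, K_max = K_max, sigma_K = sigma_K,
                 sigma_alpha = sigma_alpha, h = h,
                 env_K_coupling = env_K_coupling,
                 extinction_threshold = extinction_threshold,
                 steps = as.integer(steps)),
            class = "eh_ecoevo_config")
}

#' Generate an environmental series
#'
#' Stationary AR(1) series for the resource-distribution optimum
#' `theta_t`: `theta_t = rho * theta_{t-1} + e_t` with innovations scaled so
#' the marginal SD is `sd_env`, around a mean of 0.
#'
#' @param sd_env Marginal standard deviation (>= 0).
#' @param rho Lag-1 autocorrelation, `|rho| < 1`.
#' @param steps Series length (the simulator needs `steps + 1` values and
#'   gets them: generations `0..steps`).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `"eh_env"`: list with `theta` (length
#'   `steps + 1`), `sd_env`, `rho`, `seed`.
#' @export
generate_environment <- function(sd_env, rho = 0, steps = 500L, seed = NULL) {
  stopifnot(sd_env >= 0, abs(rho) < 1, steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- steps + 1L
  theta <- numeric(n)
  if (sd_env > 0) {
    innov_sd <- sd_env * sqrt(1 - rho^2)
    theta[1L] <- stats::rnorm(1L, 0, sd_env)
    for (t in 2:n) theta[t] <- rho * theta[t - 1L] +
        stats::rnorm(1L, 0, innov_sd)
  }
  structure(list(theta = theta, sd_env = sd_env, rho = rho, seed = seed),
            class = "eh_env")
}

#' Perturb an environmental series
#'
#' The forecaster's view of the environment: the true series plus
#' independent Gaussian noise of SD `sigma_u`, modelling both intrinsic
#' stochasticity and imperfect knowledge of future conditions.
#' `sigma_u = 0` returns the input unchanged, so forecasts then use exactly
#' the environmental series that produced the truth.
#'
#' @param env An `"eh_env"` from [generate_environment()].
#' @param sigma_u Noise SD (>= 0).
#' @param seed Optional integer seed.
#' @return An `"eh_env"` of the same length.
#' @export
perturb_environment <- function(env, sigma_u, seed = NULL) {
  stopifnot(inherits(env, "eh_env"), sigma_u >= 0)
  if (sigma_u == 0) return(env)
  if (!is.null(seed)) set.seed(seed)
  out <- env
  out$theta <- env$theta + stats::rnorm(length(env$theta), 0, sigma_u)
  out$seed <- seed
  out
}

#' Simulate the eco-evolutionary community
#'
#' @param config An [ecoevo_config()].
#' @param env An `"eh_env"` covering at least `config$steps` generations.
#' @return An object of class `"eh_community"`: list with matrices `N` and
#'   `traits` (`steps + 1` rows, one column per species) and the config.
#' @export
simulate_ecoevo <- function(config, env) {
  stopifnot(inherits(config, "eh_ecoevo_config"), inherits(env, "eh_env"))
  steps <- config$steps
  if (length(env$theta) < steps + 1L)
    stop("environment series shorter than the simulation")
  S <- config$n_species
  N <- matrix(0, steps + 1L, S)
  X <- matrix(0, steps + 1L, S)
  N[1L, ] <- config$N0
  X[1L, ] <- config$traits
  sK2 <- config$sigma_K^2
  sA2 <- config$sigma_alpha^2
  kappa <- config$env_K_coupling %||% 0
  for (t in seq_len(steps)) {
    x <- X[t, ]; n <- N[t, ]
    theta <- env$theta[t]
    K <- config$K_max * exp(kappa * theta - (x - theta)^2 / (2 * sK2))
    dx <- outer(x, x, "-")                  # dx[i, j] = x_i - x_j
    alpha <- exp(-dx^2 / (2 * sA2))
    comp <- as.vector(alpha %*% n)          # sum_j alpha_ij N_j
    g <- config$r_max * (1 - comp / K)
    n_next <- n * exp(g)
    if (any(!is.finite(n_next)))
      stop("non-finite abundance at generation ", t)
    n_next[n_next < config$extinction_threshold] <- 0
    x_next <- x
    if (config$h > 0) {
      # d g_i / d x_i: through the competition kernel and through K_i
      dalpha <- -alpha * dx / sA2           # d alpha_ij / d x_i
      dcomp <- as.vector(dalpha %*% n)
      dK <- -K * (x - theta) / sK2
      grad <- config$r_max * (-dcomp / K + comp * dK / K^2)
      x_next <- x + config$h * grad
      x_next[n_next == 0] <- x[n_next == 0]
    }
    N[t + 1L, ] <- n_next
    X[t + 1L, ] <- x_next
  }
  structure(list(N = N, traits = X, config = config, env = env),
            class = "eh_community")
}

#' @export
print.eh_community <- function(x, ...) {
  alive <- sum(x$N[nrow(x$N), ] > 0)
  cat("Community trajectory: ", ncol(x$N), " species, ", nrow(x$N) - 1L,
      " generations; ", alive, " extant at the end\n", sep = "")
  invisible(x)
}

#' Extract forecastable observables from a community trajectory
#'
#' Returns the two state variables whose predictability the case study
#' compares: the abundance of one focal species, and the total biomass of
#' the community (unit per-capita mass, i.e. the sum of abundances).
#'
#' @param traj An `"eh_community"` from [simulate_ecoevo()].
#' @param focal Focal species index.
#' @return A list with trajectories `abundance` and `biomass`.
#' @export
extract_observables <- function(traj, focal = 1L) {
  stopifnot(inherits(traj, "eh_community"),
            focal >= 1, focal <= ncol(traj$N))
  tt <- seq_len(nrow(traj$N)) - 1L
  list(abundance = trajectory(tt, traj$N[, focal], unit = "generation",
                              label = paste0("species_", focal)),
       biomass = trajectory(tt, rowSums(traj$N), unit = "generation",
                            label = "total_biomass"))
}

#' Eco-evolutionary forecast-horizon experiment
#'
#' True dynamics are simulated with evolution per `evolution_in_truth` under
#' one realised environmental series (shared by all replicates: the truth is
#' a single history); the forecasting model never evolves and sees a
#' perturbed environment with noise SD `sigma_u`. Perturbations use common
#' random numbers across uncertainty levels: replicate `i` carries one
#' standard-normal noise series that is scaled by each `sigma_u` in turn, so
#' level comparisons are paired (a variance-reduction device; marginally
#' each perturbed series equals [perturb_environment()]'s). At
#' `sigma_u = 0` every replicate is identical to the truth's environment, so
#' horizon summaries have zero width. Horizons are estimated for both
#' observables (focal-species abundance and total community biomass) by
#' windowed correlation; a replicate whose proficiency curve has fewer than
#' 2 defined points (a defunct forecast, e.g. the focal species extinct in
#' the forecast) scores a horizon of 0.
#'
#' @param config An [ecoevo_config()]; its `h` is used for the truth when
#'   `evolution_in_truth` and is always zeroed in the forecast model.
#' @param sigma_u_levels Numeric vector of environmental-uncertainty SDs.
#' @param evolution_in_truth Logical.
#' @param n_reps Replicates per level (>= 2 when any `sigma_u > 0`).
#' @param window,threshold Proficiency-curve window length and horizon
#'   threshold.
#' @param sd_env,rho Environment parameters passed to
#'   [generate_environment()].
#' @param focal Focal species index; the default picks the species with the
#'   largest mean abundance in the true dynamics (the community dominant).
#' @param band Percentile pair for horizon summaries.
#' @param seed Integer seed for the whole experiment.
#' @return An object of class `"eh_ecoevo_experiment"`: a data frame
#'   `summary` (per level x observable: median horizon, band, n infinite)
#'   plus per-level horizon distributions in `detail`.
#' @export
run_ecoevo_experiment <- function(config, sigma_u_levels = c(0, 0.1, 0.25),
                                  evolution_in_truth = TRUE, n_reps = 100L,
                                  window = 10L, threshold = 0.5,
                                  sd_env = 0.5, rho = 0.7,
                                  focal = NULL, band = c(0.25, 0.75),
                                  seed = 1L) {
  stopifnot(inherits(config, "eh_ecoevo_config"))
  if (any(sigma_u_levels > 0) && n_reps < 2)
    stop("n_reps must be >= 2 when sigma_u > 0")
  set.seed(seed)
  truth_cfg <- config
  if (!evolution_in_truth) truth_cfg$h <- 0
  env <- generate_environment(sd_env, rho, config$steps)
  truth <- simulate_ecoevo(truth_cfg, env)
  if (is.null(focal)) focal <- which.max(colMeans(truth$N))
  obs_true <- extract_observables(truth, focal)
  pred_cfg <- config
  pred_cfg$h <- 0
  # common random numbers: one noise series per replicate, scaled per level
  Z <- matrix(stats::rnorm(n_reps * (config$steps + 1L)), nrow = n_reps)

  detail <- list()
  rows <- list()
  for (su in sigma_u_levels) {
    curves <- list(abundance = vector("list", n_reps),
                   biomass = vector("list", n_reps))
    for (i in seq_len(n_reps)) {
      env_hat <- env
      if (su > 0) env_hat$theta <- env$theta + su * Z[i, ]
      fc <- simulate_ecoevo(pred_cfg, env_hat)
      obs_fc <- extract_observables(fc, focal)
      for (ob in c("abundance", "biomass")) {
        ens <- forecast_ensemble(obs_true[[ob]], obs_fc[[ob]])
        curves[[ob]][[i]] <- windowed_correlation_curve(ens,
                                                        window_length = window)
      }
    }
    for (ob in c("abundance", "biomass")) {
      h <- vapply(curves[[ob]], function(cu) {
        if (sum(!is.na(cu$mean_proficiency)) < 2L) return(0)
        horizon_from_curve(cu, threshold, crossing = "falls_below")$horizon
      }, numeric(1))
      fin <- h[is.finite(h)]
      hd <- structure(list(horizons = h,
                           median = percentile_with_inf(h, 0.5),
                           band = percentile_with_inf(h, band),
                           probs = band,
                           mean_finite = if (length(fin)) mean(fin)
                                         else NA_real_,
                           n_infinite = sum(is.infinite(h)),
                           threshold = threshold, crossing = "falls_below",
                           unit = "generation", metric = "correlation"),
                      class = "eh_horizon_dist")
      detail[[paste0(ob, "_sigma_u_", su)]] <- hd
      rows[[length(rows) + 1L]] <- data.frame(
        sigma_u = su, observable = ob, median_horizon = hd$median,
        band_low = hd$band[1L], band_high = hd$band[2L],
        n_infinite = hd$n_infinite)
    }
  }
  structure(list(summary = do.call(rbind, rows), detail = detail,
                 focal = focal, threshold = threshold,
                 evolution_in_truth = evolution_in_truth, seed = seed),
            class = "eh_ecoevo_experiment")
}

#' @export
print.eh_ecoevo_experiment <- function(x, ...) {
  cat("Eco-evolutionary forecast-horizon experiment (evolution in truth: ",
      x$evolution_in_truth, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
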