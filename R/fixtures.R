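#' Synthetic spatial community fixture
#'
#' Generates a site-by-species abundance matrix whose pairwise community
#' similarity decays with geographic distance at a controllable scale --
#' the statistical structure a distance-decay analysis of survey routes
#' assumes. Each species receives a random range centre in the arena and a
#' random range radius drawn from an exponential law with mean
#' `decay_scale_km`: the species occupies every site within the radius, so
#' the marginal occupancy probability declines exponentially with
#' site-centre distance at the decay scale, while ranges stay spatially
#' coherent (nearby sites share composition, the ingredient that makes
#' similarity decay from high values rather than hover at the mean-field
#' level). Within its range a species' expected abundance declines
#' exponentially from the centre, with log-normal scatter.
#'
#' @param n_sites,n_species Numbers of sites and species (>= 2).
#' @param arena_km Side length of the square arena (km); site coordinates
#'   are uniform in it.
#' @param decay_scale_km Mean range radius = occupancy decay scale (km);
#'   large values approach distance-independent communities.
#' @param abund0 Expected abundance at the range centre.
#' @param sdlog Log-scale SD of realised abundances.
#' @param seed Integer seed (the generator is a pure function of its
#'   arguments and the seed).
#' @return An [site_by_species()] object (planar coordinates, km).
#' @export
gen_spatial_communities <- function(n_sites = 30L, n_species = 40L,
                                    arena_km = 1000, decay_scale_km = 300,
                                    abund0 = 50, sdlog = 0.5,
                                    seed = 1L) {
  stopifnot(n_sites >= 2, n_species >= 2, decay_scale_km > 0)
  set.seed(seed)
  coords <- cbind(x = stats::runif(n_sites, 0, arena_km),
                  y = stats::runif(n_sites, 0, arena_km))
  centres <- cbind(stats::runif(n_species, 0, arena_km),
                   stats::runif(n_species, 0, arena_km))
  radius <- stats::rexp(n_species, rate = 1 / decay_scale_km)
  ab <- matrix(0L, n_sites, n_species,
               dimnames = list(paste0("site_", seq_len(n_sites)),
                               paste0("sp_", seq_len(n_species))))
  for (s in seq_len(n_species)) {
    d <- sqrt((coords[, 1L] - centres[s, 1L])^2 +
                (coords[, 2L] - centres[s, 2L])^2)
    occ <- d < radius[s]
    if (any(occ)) {
      mu <- abund0 * exp(-d[occ] / decay_scale_km)
      ab[occ, s] <- pmax(1L, as.integer(round(
        stats::rlnorm(sum(occ), meanlog = log(mu), sdlog = sdlog))))
    }
  }
  site_by_species(ab, coords, lonlat = FALSE)
}

#' Synthetic pure-birth phylogeny
#'
#' Yule (pure-birth) tree with branch lengths in time units (read as MYA by
#' the host-use pipeline) and deterministic tip labels `t1..tn`.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth_rate Speciation rate per million years (> 0); expected tree
#'   depth grows as `log(n_taxa) / birth_rate`, so the default 0.03 gives
#'   the 100-200 MY depths typical of plant family phylogenies.
#' @param seed Integer seed.
#' @return An `ape::phylo` ultrametric tree.
#' @export
gen_yule_tree <- function(n_taxa, birth_rate = 0.03, seed = 1L) {
  stopifnot(n_taxa >= 2, birth_rate > 0)
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  tree
}

#' Synthetic host-use records with phylogenetic signal
#'
#' Generates herbivore-plant use records with the statistical structure the
#' phylogenetic-horizon pipeline assumes: each herbivore gets a host breadth
#' and a set of seed (known) hosts, clustered within a random clade with
#' probability `q_clade` to mimic the roughly family-level host ranges of
#' many herbivorous insects; every remaining plant is then used with
#' probability `plogis(eta)`, where
#' `eta = beta0 + beta_breadth * breadth + beta_dist * d + epsilon`,
#' `d` is the plant's minimum patristic distance to the herbivore's seed
#' hosts, and `epsilon` is idiosyncratic (unmodelled) variation whose SD
#' decays with distance, `idio_sd * exp(-d / idio_scale)`.
#'
#' The idiosyncrasy term reflects how host use behaves near the phylogenetic
#' neighbourhood of known hosts: whether a close relative of a host is eaten
#' depends on unmeasured plant traits (chemistry, phenology), while distant
#' plants are predictably avoided. It is what makes forecast proficiency
#' *rise* with phylogenetic distance: close calls are intrinsically hard for
#' the covariate model, far calls easy. Records carry the realised
#' covariates, so the generating coefficients are recoverable by
#' [fit_host_use_model()] (exactly so when `idio_sd = 0`).
#'
#' @param tree An `ape::phylo` plant phylogeny with branch lengths (MYA).
#' @param n_herbivores Number of herbivores.
#' @param beta Length-3 numeric: intercept, breadth and distance
#'   coefficients on the logit scale (distance per MYA).
#' @param mean_breadth Mean host breadth (breadth is `1 + Poisson`).
#' @param q_clade Probability that a herbivore's seed hosts are drawn from
#'   within one clade rather than across the whole tree.
#' @param idio_sd Logit-scale SD of idiosyncratic host use at distance 0.
#' @param idio_scale Distance scale (MYA) over which idiosyncrasy decays.
#' @param seed Integer seed.
#' @return Data frame with columns `herbivore`, `plant`, `used`, `breadth`,
#'   `distance`.
#' @export
gen_host_use_table <- function(tree, n_herbivores = 20L,
                               beta = c(1, 0.4, -0.03), mean_breadth = 8,
                               q_clade = 0.8, idio_sd = 5, idio_scale = 60,
                               seed = 1L) {
  stopifnot(inherits(tree, "phylo"), length(beta) == 3L, n_herbivores >= 1,
            idio_sd >= 0, idio_scale > 0)
  set.seed(seed)
  pd <- patristic_distances(tree)
  tips <- tree$tip.label
  ntip <- length(tips)
  if (ntip < 4L) stop("at least 4 plant taxa are required")
  clades <- clade_tip_sets(tree)
  rows <- list()
  for (h in seq_len(n_herbivores)) {
    B <- 1L + stats::rpois(1L, mean_breadth - 1)
    B <- min(B, ntip - 1L)
    hosts <- if (stats::runif(1L) < q_clade) {
      big <- clades[vapply(clades, length, integer(1)) >= B]
      if (length(big)) sample(big[[sample.int(length(big), 1L)]], B)
      else sample(tips, B)
    } else sample(tips, B)
    cand <- setdiff(tips, hosts)
    d <- vapply(cand, function(p) min(pd[p, hosts]), numeric(1))
    eta <- beta[1L] + beta[2L] * B + beta[3L] * d +
      stats::rnorm(length(cand), 0, idio_sd * exp(-d / idio_scale))
    rows[[h]] <- data.frame(herbivore = paste0("h", h), plant = cand,
                            used = stats::rbinom(length(cand), 1L,
                                                 stats::plogis(eta)),
                            breadth = B, distance = unname(d))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Tip sets of every internal node (clades with >= 2 tips).
clade_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  lapply(nodes, function(nd) {
    tree$tip.label[tip_descendants(tree, nd)]
  })
}

tip_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    if (nd <= ntip) out <- c(out, nd)
    else stack <- c(stack, tree$edge[tree$edge[, 1L] == nd, 2L])
  }
  out
}

#' Replicate proficiency curves with a known horizon
#'
#' Known-answer fixture for the horizon estimators: noisy replicate curves
#' whose noiseless version crosses `threshold` exactly at `true_horizon`.
#' The `"exponential"` family uses `exp(-d / tau)` with `tau` calibrated to
#' the crossing; `"linear"` declines from 1 at distance 0 through the
#' crossing. Gaussian noise of SD `noise_sd` is added independently per
#' point and replicate (clipped to the correlation range).
#'
#' @param true_horizon Crossing distance of the noiseless curve (> 0).
#' @param family `"exponential"` or `"linear"`.
#' @param noise_sd Noise SD (>= 0).
#' @param n_reps Number of replicate curves.
#' @param threshold Threshold crossed at `true_horizon` (default 0.5).
#' @param distances Curve support; must bracket `true_horizon`.
#' @param seed Integer seed.
#' @return List of [proficiency_curve()] objects.
#' @export
gen_replicate_curves <- function(true_horizon,
                                 family = c("exponential", "linear"),
                                 noise_sd = 0, n_reps = 1L,
                                 threshold = 0.5,
                                 distances = seq(0, 2.5 * true_horizon,
                                                 length.out = 26L),
                                 seed = 1L) {
  family <- match.arg(family)
  stopifnot(true_horizon > 0, threshold > 0, threshold < 1, noise_sd >= 0)
  if (true_horizon <= min(distances) || true_horizon >= max(distances))
    stop("`true_horizon` must lie inside the curve support")
  set.seed(seed)
  base <- if (family == "exponential") {
    tau <- true_horizon / log(1 / threshold)
    exp(-distances / tau)
  } else {
    pmax(-1, 1 - distances * (1 - threshold) / true_horizon)
  }
  lapply(seq_len(n_reps), function(i) {
    v <- base + stats::rnorm(length(base), 0, noise_sd)
    proficiency_curve(distances, pmin(1, pmax(-1, v)),
                      metric = "correlation", higher_is_better = TRUE,
                      unit = "arbitrary")
  })
}
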