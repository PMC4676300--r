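#' Sorensen similarity of two species sets
#'
#' `2 |A intersect B| / (|A| + |B|)`: the proportion of species occurrences
#' that one community predicts correctly in the other.
#'
#' @param a,b Character (or other atomic) vectors of species identities;
#'   duplicates are ignored.
#' @return Similarity in \[0, 1\].
#' @examples
#' sorensen(c("s1", "s2", "s3"), c("s2", "s3", "s4"))  # 2/3
#' @export
sorensen <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0)
    stop("both species sets are empty")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Pearson correlation of square-root transformed abundances
#'
#' @param a,b Non-negative abundance vectors of equal length (>= 3).
#' @return Correlation in \[-1, 1\], or `NA` when either transformed vector
#'   is constant.
#' @export
sqrt_abundance_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3, all(a >= 0), all(b >= 0))
  safe_cor(sqrt(a), sqrt(b))
}

#' Site-by-species matrix with coordinates
#'
#' @param abundance Non-negative matrix, rows = sites, columns = species;
#'   row names are site ids.
#' @param coords Data frame or matrix with one row per site and two columns
#'   (x/y in km, or longitude/latitude when `lonlat = TRUE`).
#' @param lonlat Logical; coordinates are longitude/latitude and pairwise
#'   distances are great-circle (haversine) in km. Default planar Euclidean
#'   in km.
#' @return An object of class `"eh_sites"`.
#' @export
site_by_species <- function(abundance, coords, lonlat = FALSE) {
  abundance <- as.matrix(abundance)
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  if (nrow(abundance) != nrow(coords))
    stop("`abundance` and `coords` must describe the same sites")
  if (any(abundance < 0)) stop("abundances must be non-negative")
  if (anyDuplicated(coords)) stop("site coordinates must be unique")
  if (is.null(rownames(abundance)))
    rownames(abundance) <- paste0("site_", seq_len(nrow(abundance)))
  structure(list(abundance = abundance, coords = coords,
                 lonlat = isTRUE(lonlat)),
            class = "eh_sites")
}

site_distances <- function(sites) {
  if (sites$lonlat) {
    n <- nrow(sites$coords)
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      m[i, (i + 1L):n] <- geosphere::distHaversine(
        sites$coords[i, , drop = FALSE],
        sites$coords[(i + 1L):n, , drop = FALSE]) / 1000
    }
    m + t(m)
  } else {
    as.matrix(stats::dist(sites$coords))
  }
}

#' Distance-decay of community similarity
#'
#' Computes a similarity for every pair of sites (Sorensen on presence sets,
#' or Pearson correlation of square-root abundances), bins the pairs by
#' geographic distance, and returns per-bin mean similarity as a
#' proficiency curve over km. Read as a forecast: the similarity is the
#' proficiency with which one community predicts another a given distance
#' away, and the spatial forecast horizon is where the curve falls below the
#' threshold.
#'
#' @param sites An [site_by_species()].
#' @param metric `"sorensen"` or `"sqrt_pearson"`.
#' @param bins Number of equal-width distance bins, or a vector of bin
#'   edges covering the observed pairwise-distance range.
#' @return An [proficiency_curve()] (unit km); empty bins yield `NA`.
#' @export
distance_decay_curve <- function(sites, metric = c("sorensen", "sqrt_pearson"),
                                 bins = 15L) {
  metric <- match.arg(metric)
  stopifnot(inherits(sites, "eh_sites"))
  n <- nrow(sites$abundance)
  if (n < 2L) stop("at least 2 sites are required")
  dm <- site_distances(sites)
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  dist_ij <- dm[upper.tri(dm)]
  sim_ij <- vapply(seq_len(nrow(pairs)), function(k) {
    ai <- sites$abundance[pairs[k, 1L], ]
    aj <- sites$abundance[pairs[k, 2L], ]
    if (metric == "sorensen") {
      si <- colnames(sites$abundance)[ai > 0]
      sj <- colnames(sites$abundance)[aj > 0]
      if (length(si) == 0 && length(sj) == 0) return(NA_real_)
      sorensen(si, sj)
    } else {
      sqrt_abundance_correlation(ai, aj)
    }
  }, numeric(1))
  metric_name <- if (metric == "sorensen") "sorensen" else "sqrt_pearson"
  if (diff(range(dist_ij)) == 0) {
    # all pairs at one distance (e.g. two sites): a single-point curve
    return(proficiency_curve(dist_ij[1L], mean(sim_ij, na.rm = TRUE),
                             metric = metric_name, higher_is_better = TRUE,
                             unit = "km"))
  }
  edges <- if (length(bins) == 1L)
    seq(min(dist_ij), max(dist_ij), length.out = bins + 1L) else sort(bins)
  idx <- cut(dist_ij, edges, include.lowest = TRUE, labels = FALSE)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  means <- vapply(seq_along(mids), function(b) {
    v <- sim_ij[idx == b & !is.na(idx)]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  proficiency_curve(mids, means, metric = metric_name,
                    higher_is_better = TRUE, unit = "km")
}

#' Patristic distance matrix of a phylogeny
#'
#' Sum of branch lengths along the tree path between every pair of tips,
#' computed by accumulating each tip's root-to-tip path and subtracting
#' twice the shared portion.
#'
#' @param tree An `ape::phylo` tree with branch lengths and unique tip
#'   labels (branch lengths in millions of years for the host-use
#'   pipeline).
#' @return Symmetric matrix with zero diagonal, tip labels as dimnames.
#' @export
patristic_distances <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode); plen <- numeric(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  plen[tree$edge[, 2L]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  # depth of every node from the root
  depth <- rep(NA_real_, nnode); depth[root] <- 0
  # children ordering: process edges in preorder via repeated passes
  ord <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]
  repeat {
    todo <- which(is.na(depth[ord[, 2L]]) & !is.na(depth[ord[, 1L]]))
    if (!length(todo)) break
    depth[ord[todo, 2L]] <- depth[ord[todo, 1L]] +
      plen[ord[todo, 2L]]
  }
  # ancestor paths per tip
  paths <- lapply(seq_len(ntip), function(i) {
    p <- i
    while (p != root) { p <- parent[p]; i <- c(i, p) }
    i
  })
  m <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1L)) {
    for (j in (i + 1L):ntip) {
      # shared ancestors form a root-ward chain; the MRCA is the deepest
      shared <- intersect(paths[[i]], paths[[j]])
      mrca <- shared[which.max(depth[shared])]
      m[i, j] <- m[j, i] <- depth[i] + depth[j] - 2 * depth[mrca]
    }
  }
  m
}

#' Fit the binomial host-use model
#'
#' Logistic regression of host use on the herbivore's host breadth and the
#' phylogenetic distance of the candidate plant from its nearest known host,
#' fitted by iteratively reweighted least squares. Complete separation is
#' reported as an error unless `ridge = TRUE`, which switches to a
#' Newton-IRLS fit with a small ridge penalty (1e-6) on the coefficients.
#'
#' @param records Data frame with columns `used` (0/1), `breadth` (>= 1)
#'   and `distance` (>= 0, MYA), one row per herbivore x candidate plant.
#' @param log_breadth Use `log(breadth)` as the covariate instead of the raw
#'   count.
#' @param ridge Logical, see Description.
#' @return An object of class `"eh_hostuse_model"`: list with
#'   `coefficients` (intercept, breadth, distance on the logit scale),
#'   `se`, `converged`, `log_breadth`, and the `glm` fit when applicable.
#' @export
fit_host_use_model <- function(records, log_breadth = FALSE, ridge = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("used", "breadth", "distance") %in% names(records)))
  if (nrow(records) < 10L) stop("at least 10 records are required")
  if (length(unique(records$used)) < 2L)
    stop("both outcome classes must be present")
  b <- if (log_breadth) log(records$breadth) else records$breadth
  X <- cbind(1, b, records$distance)
  y <- records$used
  if (qr(X)$rank < 3L) stop("predictors are collinear")
  if (!ridge) {
    fit <- stats::glm(y ~ b + records$distance, family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-8,
                                                   maxit = 50L))
    p <- stats::fitted(fit)
    if (!fit$converged || any(p > 1 - 1e-10) || any(p < 1e-10)) {
      if (!fit$converged)
        stop("IRLS did not converge; consider `ridge = TRUE`")
      if (max(p) > 1 - 1e-10 && min(p) < 1e-10)
        stop("complete separation suspected; refit with `ridge = TRUE`")
    }
    co <- unname(stats::coef(fit))
    se <- unname(sqrt(diag(stats::vcov(fit))))
    conv <- fit$converged
  } else {
    co <- ridge_logistic(X, y, lambda = 1e-6)
    se <- rep(NA_real_, 3L)
    fit <- NULL
    conv <- TRUE
  }
  structure(list(coefficients = stats::setNames(co, c("intercept", "breadth",
                                                      "distance")),
                 se = se, converged = conv, log_breadth = log_breadth,
                 glm_fit = fit),
            class = "eh_hostuse_model")
}

# Newton-IRLS logistic regression with an L2 penalty on all coefficients.
ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 50L,
                           tol = 1e-8) {
  beta <- rep(0, ncol(X))
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    H <- crossprod(X, X * W) + diag(lambda, ncol(X))
    g <- crossprod(X, y - p) - lambda * beta
    beta <- beta + solve(H, g)
    dev <- -2 * sum(y * stats::plogis(as.vector(X %*% beta), log.p = TRUE) +
                      (1 - y) * stats::plogis(-as.vector(X %*% beta),
                                              log.p = TRUE))
    if (is.finite(dev_old) && abs(dev_old - dev) / (abs(dev) + 0.1) < tol)
      break
    dev_old <- dev
  }
  as.vector(beta)
}

#' Predict host-use probabilities
#'
#' @param model An `"eh_hostuse_model"`.
#' @param records Data frame with `breadth` and `distance` columns.
#' @return Probabilities in (0, 1).
#' @export
predict_host_use <- function(model, records) {
  stopifnot(inherits(model, "eh_hostuse_model"))
  b <- if (model$log_breadth) log(records$breadth) else records$breadth
  eta <- unname(model$coefficients[1L] + model$coefficients[2L] * b +
                  model$coefficients[3L] * records$distance)
  stats::plogis(eta)
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) formulation: the probability that a
#' randomly chosen positive record outscores a randomly chosen negative one,
#' with ties counted one half. Invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Slice-wise AUC over phylogenetic distance
#'
#' Partitions prediction records into distance slices and computes the AUC
#' of the predictions within each slice, giving forecast proficiency as a
#' function of phylogenetic distance. `"equal_count"` slicing (default)
#' places quantile edges so slices carry similar record counts;
#' `"equal_width"` uses bins of equal distance width. Slices lacking both
#' outcome classes yield `NA` and are skipped (never interpolated) by the
#' horizon estimators. Host-use proficiency typically *rises* with
#' phylogenetic distance, so the matching horizon call is
#' `horizon_from_curve(..., crossing = "rises_above")`.
#'
#' @param predictions Numeric scores (e.g. from [predict_host_use()]).
#' @param labels Binary outcomes.
#' @param distances Phylogenetic distances (MYA), one per record.
#' @param n_slices Number of slices (>= 2).
#' @param scheme `"equal_count"` or `"equal_width"`.
#' @return An [proficiency_curve()] (unit MYA, metric `"auc"`) with
#'   attributes `"counts"` (records per slice) and `"edges"`.
#' @export
slice_proficiency_curve <- function(predictions, labels, distances,
                                    n_slices = 12L,
                                    scheme = c("equal_count", "equal_width")) {
  scheme <- match.arg(scheme)
  stopifnot(length(predictions) == length(labels),
            length(labels) == length(distances), n_slices >= 2)
  if (diff(range(distances)) == 0)
    stop("degenerate distance range: all records at one distance")
  edges <- if (scheme == "equal_count") {
    e <- stats::quantile(distances, probs = seq(0, 1,
                                                length.out = n_slices + 1L),
                         names = FALSE)
    # collapse edges closer than numerical resolution (heavy ties at a
    # single distance produce duplicate quantiles), keeping the true
    # maximum so every record falls in a slice
    emax <- e[length(e)]
    e <- e[c(TRUE, diff(e) > 1e-9 * diff(range(distances)))]
    e[length(e)] <- emax
    if (length(e) < 3L) stop("too few distinct distances for slicing")
    e
  } else {
    seq(min(distances), max(distances), length.out = n_slices + 1L)
  }
  idx <- cut(distances, edges, include.lowest = TRUE, labels = FALSE)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  counts <- tabulate(idx, nbins = length(mids))
  aucs <- vapply(seq_along(mids), function(s) {
    sel <- !is.na(idx) & idx == s
    if (sum(sel) == 0L) return(NA_real_)
    l <- labels[sel]
    if (length(unique(l)) < 2L) return(NA_real_)
    auc(predictions[sel], l)
  }, numeric(1))
  cv <- proficiency_curve(mids, aucs, metric = "auc",
                          higher_is_better = TRUE, unit = "MYA")
  attr(cv, "counts") <- counts
  attr(cv, "edges") <- edges
  cv
}

#' Minimum patristic distance to a set of known hosts
#'
#' Operationalises "phylogenetic distance from another known host" as the
#' minimum patristic distance from the candidate plant to any of the
#' herbivore's known hosts.
#'
#' @param pd Patristic distance matrix (from [patristic_distances()]).
#' @param plant Candidate plant tip label.
#' @param hosts Character vector of known-host tip labels.
#' @return Non-negative scalar (MYA).
#' @export
min_host_distance <- function(pd, plant, hosts) {
  hosts <- setdiff(hosts, plant)
  if (!length(hosts)) stop("no known hosts other than the candidate")
  min(pd[plant, hosts])
}
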