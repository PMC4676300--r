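#' Read trajectories from CSV
#'
#' Expects a header `time,value` with an optional `replicate` column. With a
#' replicate column, one trajectory per replicate label is returned (in a
#' named list); naming one of the labels as `truth_label` instead builds a
#' [forecast_ensemble()] with the remaining series as forecasts.
#'
#' @param path CSV file path.
#' @param truth_label Optional replicate label to treat as the truth.
#' @param unit Time-axis unit passed to [trajectory()].
#' @return A trajectory, a named list of trajectories, or an ensemble.
#' @export
read_trajectories <- function(path, truth_label = NULL, unit = "generation") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "value") %in% names(df)))
    stop("CSV must have columns `time,value[,replicate]`")
  make_one <- function(sub, label) {
    bad <- which(diff(sub$time) <= 0)
    if (length(bad))
      stop("non-monotone time at row ", bad[1L] + 1L,
           if (nzchar(label)) paste0(" of replicate '", label, "'"))
    trajectory(sub$time, sub$value, unit = unit, label = label)
  }
  if (!"replicate" %in% names(df)) return(make_one(df, ""))
  labs <- unique(df$replicate)
  trajs <- lapply(labs, function(l)
    make_one(df[df$replicate == l, , drop = FALSE], as.character(l)))
  names(trajs) <- labs
  if (is.null(truth_label)) return(trajs)
  if (!truth_label %in% labs)
    stop("truth label '", truth_label, "' not found")
  forecast_ensemble(trajs[[truth_label]], trajs[names(trajs) != truth_label])
}

#' Write trajectories to CSV
#'
#' @param x A trajectory, list of trajectories, or ensemble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(x, path) {
  if (inherits(x, "eh_trajectory")) {
    df <- data.frame(time = x$times, value = x$values)
  } else {
    if (inherits(x, "eh_ensemble")) {
      lst <- c(list(truth = x$truth), x$forecasts)
      if (is.null(names(lst)) || any(names(lst)[-1L] == ""))
        names(lst) <- c("truth", paste0("f", seq_along(x$forecasts)))
    } else lst <- x
    if (is.null(names(lst)))
      names(lst) <- paste0("rep_", seq_along(lst))
    df <- do.call(rbind, lapply(names(lst), function(nm)
      data.frame(time = lst[[nm]]$times, value = lst[[nm]]$values,
                 replicate = nm)))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a site-by-species matrix with coordinates
#'
#' @param matrix_path CSV with a `site` column plus one column per species
#'   (rows = sites, non-negative counts).
#' @param coords_path CSV with columns `site,x,y` and an optional `crs`
#'   column (value `"lonlat"` switches distances to great-circle km).
#' @return An [site_by_species()].
#' @export
read_community <- function(matrix_path, coords_path) {
  m <- utils::read.csv(matrix_path, stringsAsFactors = FALSE)
  co <- utils::read.csv(coords_path, stringsAsFactors = FALSE)
  if (!"site" %in% names(m)) stop("matrix CSV needs a `site` column")
  if (!all(c("site", "x", "y") %in% names(co)))
    stop("coordinates CSV needs columns `site,x,y`")
  missing_coord <- setdiff(m$site, co$site)
  extra_coord <- setdiff(co$site, m$site)
  if (length(missing_coord) || length(extra_coord))
    stop("site ids do not match; missing coordinates for: ",
         paste(missing_coord, collapse = ", "),
         if (length(extra_coord)) paste0("; unmatched coordinates: ",
                                         paste(extra_coord, collapse = ", ")))
  ab <- as.matrix(m[, setdiff(names(m), "site"), drop = FALSE])
  rownames(ab) <- m$site
  if (any(ab < 0)) stop("negative abundance in the matrix")
  co <- co[match(m$site, co$site), , drop = FALSE]
  lonlat <- "crs" %in% names(co) && any(co$crs == "lonlat")
  site_by_species(ab, co[, c("x", "y")], lonlat = lonlat)
}

#' Write a site-by-species matrix and its coordinates
#'
#' @param sites An [site_by_species()].
#' @param matrix_path,coords_path Output CSV paths.
#' @return `matrix_path`, invisibly.
#' @export
write_community <- function(sites, matrix_path, coords_path) {
  stopifnot(inherits(sites, "eh_sites"))
  df <- data.frame(site = rownames(sites$abundance),
                   as.data.frame(sites$abundance), check.names = FALSE)
  utils::write.csv(df, matrix_path, row.names = FALSE)
  co <- data.frame(site = rownames(sites$abundance),
                   x = sites$coords[, 1L], y = sites$coords[, 2L])
  if (sites$lonlat) co$crs <- "lonlat"
  utils::write.csv(co, coords_path, row.names = FALSE)
  invisible(matrix_path)
}

#' Read a Newick tree for the phylogenetic pipeline
#'
#' @param path Newick file with branch lengths.
#' @return An `ape::phylo` object; missing branch lengths or duplicate tip
#'   labels are errors, never silently defaulted.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; patristic distances are undefined")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Write a proficiency curve to CSV
#'
#' Columns `distance,mean[,lower,upper][,rep_*]`.
#'
#' @param curve An [proficiency_curve()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "eh_curve"))
  df <- data.frame(distance = curve$distances,
                   mean = curve$mean_proficiency)
  if (!is.null(curve$band)) {
    df$lower <- curve$band$lower
    df$upper <- curve$band$upper
  }
  if (!is.null(curve$replicates)) {
    reps <- t(curve$replicates)
    colnames(reps) <- paste0("rep_", seq_len(ncol(reps)))
    df <- cbind(df, reps)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a proficiency curve from CSV
#'
#' @param path CSV written by [write_curve_csv()].
#' @param metric,higher_is_better,unit Curve metadata (CSV stores values
#'   only).
#' @return An [proficiency_curve()].
#' @export
read_curve_csv <- function(path, metric = "correlation",
                           higher_is_better = TRUE, unit = "arbitrary") {
  df <- utils::read.csv(path)
  if (!all(c("distance", "mean") %in% names(df)))
    stop("curve CSV needs columns `distance,mean`")
  repcols <- grep("^rep_", names(df), value = TRUE)
  reps <- if (length(repcols)) t(as.matrix(df[, repcols, drop = FALSE]))
          else NULL
  band <- if (all(c("lower", "upper") %in% names(df)))
    list(lower = df$lower, upper = df$upper, probs = c(NA, NA)) else NULL
  proficiency_curve(df$distance, df$mean, metric = metric,
                    higher_is_better = higher_is_better, unit = unit,
                    replicates = reps, band = band)
}

# FNV-1a-style rolling hash of a character scalar, truncated to 31 bits so
# every intermediate fits in an R integer; 8-hex-digit digest.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 216613626
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}

# Stable digest of a configuration-like list.
config_digest <- function(x) {
  fnv1a(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE))
}

#' Serialise a horizon estimate or distribution to a JSON report
#'
#' JSON has no representation of infinity, so infinite horizons are written
#' as the string `"inf"` with a sidecar boolean `is_infinite`.
#'
#' @param x An `"eh_horizon"` or `"eh_horizon_dist"`.
#' @param path Output JSON path; `NULL` returns the report list instead.
#' @param seed Seed recorded in the report.
#' @param config Optional configuration list; its digest is recorded.
#' @return The report list, invisibly when written.
#' @export
write_horizon_json <- function(x, path = NULL, seed = NA, config = NULL) {
  enc <- function(v) if (is.infinite(v)) "inf" else v
  rep <- if (inherits(x, "eh_horizon")) {
    list(metric = x$metric, threshold = x$threshold, crossing = x$crossing,
         horizon = enc(x$horizon), is_infinite = is.infinite(x$horizon),
         unit = x$unit,
         interval = if (!is.null(x$interval))
           lapply(as.list(x$interval), enc))
  } else if (inherits(x, "eh_horizon_dist")) {
    list(metric = x$metric, threshold = x$threshold, crossing = x$crossing,
         horizon = enc(x$median), is_infinite = is.infinite(x$median),
         unit = x$unit,
         interval = lapply(as.list(x$band), enc),
         band_probs = x$probs,
         n_replicates = length(x$horizons),
         n_infinite = x$n_infinite,
         mean_finite = x$mean_finite)
  } else stop("`x` must be a horizon estimate or distribution")
  rep$seed <- seed
  rep$package_version <- as.character(utils::packageVersion("ecohorizon"))
  if (!is.null(config)) rep$config_digest <- config_digest(config)
  if (is.null(path)) return(rep)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(rep)
}
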