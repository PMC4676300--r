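test_that("generators are pure functions of their seed", {
  expect_identical(gen_spatial_communities(seed = 5)$abundance,
                   gen_spatial_communities(seed = 5)$abundance)
  expect_identical(ape::write.tree(gen_yule_tree(20, seed = 6)),
                   ape::write.tree(gen_yule_tree(20, seed = 6)))
  tr <- gen_yule_tree(15, seed = 7)
  expect_identical(gen_host_use_table(tr, seed = 8),
                   gen_host_use_table(tr, seed = 8))
  c1 <- gen_replicate_curves(5, noise_sd = 0.1, n_reps = 3, seed = 9)
  c2 <- gen_replicate_curves(5, noise_sd = 0.1, n_reps = 3, seed = 9)
  expect_identical(lapply(c1, `[[`, "mean_proficiency"),
                   lapply(c2, `[[`, "mean_proficiency"))
})

test_that("spatial similarity is distance-free in the large-scale limit and decaying otherwise", {
  slope_of <- function(scale, s) {
    sites <- gen_spatial_communities(decay_scale_km = scale, seed = s)
    cv <- distance_decay_curve(sites, "sorensen", bins = 8)
    ok <- !is.na(cv$mean_proficiency)
    unname(coef(lm(cv$mean_proficiency[ok] ~ cv$distances[ok]))[2])
  }
  big <- sapply(1:50, function(s) slope_of(1e5, s))
  expect_lt(abs(mean(big)), 2e-5)  # ~0 similarity change per km

  small_ordered <- sapply(1:50, function(s) {
    sites <- gen_spatial_communities(decay_scale_km = 100, seed = s)
    cv <- distance_decay_curve(sites, "sorensen", bins = 8)
    v <- cv$mean_proficiency[!is.na(cv$mean_proficiency)]
    head(v, 1) > tail(v, 1)
  })
  expect_gte(mean(small_ordered), 0.95)
})

test_that("pure-birth trees are ultrametric, round-trip, and deepen with taxa", {
  two <- gen_yule_tree(2, seed = 1)
  depths <- ape::node.depth.edgelength(two)[1:2]
  expect_equal(depths[1], depths[2], tolerance = 1e-9)

  tr <- gen_yule_tree(25, seed = 3)
  tmp <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, tmp)
  back <- read_tree(tmp)
  expect_equal(patristic_distances(tr)[tr$tip.label, tr$tip.label],
               patristic_distances(back)[tr$tip.label, tr$tip.label],
               tolerance = 1e-6)

  depth_of <- function(n, s) max(ape::node.depth.edgelength(
    gen_yule_tree(n, seed = s)))
  d10 <- sapply(1:100, function(s) depth_of(10, s))
  d40 <- sapply(1:100, function(s) depth_of(40, s + 1000))
  expect_gt(mean(d40), mean(d10))
})

test_that("host-use tables carry the generating signal", {
  # no covariate effects and no idiosyncrasy: flat use, AUC ~ 0.5
  aucs <- c()
  for (s in 1:50) {
    tree <- gen_yule_tree(25, seed = s)
    tab <- gen_host_use_table(tree, n_herbivores = 10,
                              beta = c(0, 0, 0), idio_sd = 0, seed = s + 200)
    sc <- tryCatch(suppressWarnings(
      slice_proficiency_curve(runif(nrow(tab)), tab$used, tab$distance,
                              n_slices = 4)),
      error = function(e) NULL)
    if (!is.null(sc)) aucs <- c(aucs, sc$mean_proficiency)
  }
  expect_equal(mean(aucs, na.rm = TRUE), 0.5, tolerance = 0.03)

  # strong distance penalty: nearest slice has the highest use rate
  nearest_highest <- sapply(1:50, function(s) {
    tree <- gen_yule_tree(30, seed = s)
    tab <- gen_host_use_table(tree, n_herbivores = 15,
                              beta = c(1, 0.1, -0.05), idio_sd = 0,
                              seed = s + 400)
    qs <- unique(quantile(tab$distance, c(0, 0.25, 0.5, 0.75, 1)))
    rate <- tapply(tab$used, cut(tab$distance, qs, include.lowest = TRUE),
                   mean)
    which.max(rate) == 1
  })
  expect_gte(mean(nearest_highest), 0.9)
})

test_that("replicate-curve fixtures cross at the stated horizon", {
  for (fam in c("exponential", "linear")) {
    cu <- gen_replicate_curves(6, fam, noise_sd = 0, n_reps = 1,
                               threshold = 0.5)[[1]]
    expect_equal(horizon_from_curve(cu, 0.5)$horizon, 6, tolerance = 1e-6,
                 info = fam)
  }
  curves <- gen_replicate_curves(6, "exponential", noise_sd = 0.05,
                                 n_reps = 500, threshold = 0.5, seed = 77)
  hd <- horizon_distribution(curves, 0.5)
  expect_equal(hd$median, 6, tolerance = 0.05 * 15)  # 5% of the curve span
})
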