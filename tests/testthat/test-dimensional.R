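test_that("similarity measures follow their definitions and symmetry", {
  expect_equal(sorensen(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(sorensen(c("a", "b"), c("c", "d")), 0)
  expect_equal(sorensen(c("s1", "s2", "s3"), c("s2", "s3", "s4")), 4 / 6)
  expect_equal(sorensen(c("s2", "s3", "s4"), c("s1", "s2", "s3")), 4 / 6)
  expect_error(sorensen(character(0), character(0)), "empty")

  a <- c(1, 4, 9, 16, 25)
  expect_equal(sqrt_abundance_correlation(a, a), 1)
  expect_equal(sqrt_abundance_correlation(a, 4 * a), 1)
  set.seed(8)
  b <- rpois(5, 10)
  expect_equal(sqrt_abundance_correlation(a, b),
               oracle_pearson(sqrt(a), sqrt(b)), tolerance = 1e-12)
  expect_equal(sqrt_abundance_correlation(a, b),
               sqrt_abundance_correlation(b, a))
  expect_true(is.na(sqrt_abundance_correlation(a, rep(4, 5))))
})

test_that("distance-decay bins equal a pair-enumeration oracle", {
  sites <- gen_spatial_communities(n_sites = 20, n_species = 15, seed = 21)
  cv <- distance_decay_curve(sites, "sorensen", bins = 6)
  dm <- as.matrix(dist(sites$coords))
  sims <- c(); dd <- c()
  for (i in 1:19) for (j in (i + 1):20) {
    si <- colnames(sites$abundance)[sites$abundance[i, ] > 0]
    sj <- colnames(sites$abundance)[sites$abundance[j, ] > 0]
    sims <- c(sims, 2 * length(intersect(si, sj)) /
                (length(si) + length(sj)))
    dd <- c(dd, dm[i, j])
  }
  edges <- seq(min(dd), max(dd), length.out = 7)
  for (b in 1:6) {
    lo <- edges[b]; hi <- edges[b + 1]
    sel <- if (b == 1) dd >= lo & dd <= hi else dd > lo & dd <= hi
    if (any(sel))
      expect_equal(cv$mean_proficiency[b], mean(sims[sel]), tolerance = 1e-12)
  }

  # degenerate inputs
  same <- site_by_species(matrix(1, 3, 4,
                                 dimnames = list(NULL, paste0("s", 1:4))),
                          cbind(c(0, 1, 2), c(0, 0, 0)))
  cu <- distance_decay_curve(same, "sorensen", bins = 2)
  expect_true(all(cu$mean_proficiency[!is.na(cu$mean_proficiency)] == 1))
  two <- site_by_species(matrix(c(1, 0, 1, 1), 2, 2,
                                dimnames = list(NULL, c("a", "b"))),
                         cbind(c(0, 3), c(0, 4)))
  cu2 <- distance_decay_curve(two, "sorensen", bins = 1)
  expect_equal(cu2$distances, 5)
})

test_that("patristic distances match ape and a breadth-first oracle", {
  cherry <- ape::read.tree(text = "(A:1,B:2);")
  pd <- patristic_distances(cherry)
  expect_equal(pd["A", "B"], 3)

  for (s in 1:5) {
    set.seed(s)
    tree <- ape::rtree(8, rooted = TRUE)
    pd <- patristic_distances(tree)
    expect_equal(pd, oracle_patristic(tree), tolerance = 1e-12)
    expect_equal(pd, t(pd))
    expect_true(all(diag(pd) == 0))
    expect_equal(pd[tree$tip.label, tree$tip.label],
                 as.matrix(stats::cophenetic(tree))[tree$tip.label,
                                                    tree$tip.label],
                 tolerance = 1e-10)
  }
  noblen <- ape::read.tree(text = "(A,B);")
  expect_error(patristic_distances(noblen), "branch lengths")
})

test_that("the host-use GLM recovers known coefficients", {
  set.seed(77)
  n <- 5000
  breadth <- sample(1:10, n, replace = TRUE)
  distance <- runif(n, 0, 200)
  eta <- 0 + 0.5 * breadth - 0.02 * distance
  rec <- data.frame(used = rbinom(n, 1, plogis(eta)),
                    breadth = breadth, distance = distance)
  fit <- fit_host_use_model(rec)
  truth <- c(0, 0.5, -0.02)
  expect_true(all(abs(fit$coefficients - truth) < 3 * fit$se))

  # null data: no coefficient further than 3 SE from zero
  rec0 <- data.frame(used = rbinom(n, 1, 0.3),
                     breadth = breadth, distance = distance)
  fit0 <- fit_host_use_model(rec0)
  expect_true(all(abs(fit0$coefficients[2:3]) < 3 * fit0$se[2:3]))

  one_class <- data.frame(used = rep(1, 50), breadth = 1:50,
                          distance = runif(50))
  expect_error(fit_host_use_model(one_class), "both outcome classes")
})

test_that("separation is detected and the ridge fallback is close to the MLE direction", {
  set.seed(19)
  sep <- data.frame(used = rep(c(0, 1), each = 25),
                    breadth = c(rnorm(25, 2), rnorm(25, 20)),
                    distance = runif(50, 0, 10))
  expect_error(suppressWarnings(fit_host_use_model(sep)), "ridge")
  fr <- fit_host_use_model(sep, ridge = TRUE)
  expect_gt(fr$coefficients["breadth"], 0)
  # ridge fit matches glm closely on a well-behaved problem
  set.seed(5)
  ok <- data.frame(used = rbinom(500, 1, 0.4), breadth = rnorm(500),
                   distance = rnorm(500))
  f1 <- fit_host_use_model(ok)
  f2 <- fit_host_use_model(ok, ridge = TRUE)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-4)
})

test_that("prediction is the inverse logit of the linear predictor", {
  m <- structure(list(coefficients = c(intercept = 0, breadth = 0,
                                       distance = 0),
                      log_breadth = FALSE),
                 class = "eh_hostuse_model")
  rec <- data.frame(breadth = 1:5, distance = seq(0, 100, 25))
  expect_true(all(predict_host_use(m, rec) == 0.5))

  m2 <- structure(list(coefficients = c(intercept = -1, breadth = 0.3,
                                        distance = -0.02),
                       log_breadth = FALSE),
                  class = "eh_hostuse_model")
  expect_equal(predict_host_use(m2, data.frame(breadth = 4, distance = 50)),
               1 / (1 + exp(-(-1 + 0.3 * 4 - 0.02 * 50))), tolerance = 1e-12)
  p <- predict_host_use(m2, data.frame(breadth = seq(1, 100, 1),
                                       distance = 0))
  expect_true(all(diff(p) > 0) && all(p > 0 & p < 1))
})

test_that("AUC equals brute-force pair enumeration and is rank-invariant", {
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(auc(rep(0.4, 8), rep(c(0, 1), 4)), 0.5)
  sc <- c(0.1, 0.4, 0.35, 0.8); lb <- c(0, 0, 1, 1)
  expect_equal(auc(sc, lb), oracle_auc(sc, lb), tolerance = 1e-12)
  set.seed(12)
  for (i in 1:10) {
    s <- round(runif(30), 2)        # deliberate ties
    l <- rbinom(30, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(auc(s, l), oracle_auc(s, l), tolerance = 1e-12)
    expect_equal(auc(qlogis(pmin(pmax(s, 0.01), 0.99)), l),
                 auc(pmin(pmax(s, 0.01), 0.99), l), tolerance = 1e-12)
  }
  expect_error(auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC matches pROC on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(3)
  s <- runif(200); l <- rbinom(200, 1, plogis(3 * s - 1.5))
  expect_equal(auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("slice curves partition records and flag degenerate inputs", {
  set.seed(14)
  n <- 600
  d <- c(runif(n / 2, 0, 50), runif(n / 2, 50, 300))
  p <- plogis(2 - 0.02 * d)
  y <- rbinom(n, 1, p)
  sc <- slice_proficiency_curve(p, y, d, n_slices = 6)
  expect_equal(sum(attr(sc, "counts")), n)
  expect_equal(length(sc$distances), length(attr(sc, "counts")))
  expect_true(all(diff(attr(sc, "edges")) > 0))
  sw <- slice_proficiency_curve(p, y, d, n_slices = 6, scheme = "equal_width")
  expect_equal(diff(attr(sw, "edges")), rep(diff(range(d)) / 6, 6),
               tolerance = 1e-9)
  expect_error(slice_proficiency_curve(p, y, rep(3, n)), "degenerate")
})

test_that("min host distance takes the minimum over the host set", {
  tree <- gen_yule_tree(12, seed = 2)
  pd <- patristic_distances(tree)
  hosts <- c("t1", "t5", "t9")
  expect_equal(min_host_distance(pd, "t3", hosts),
               min(pd["t3", "t1"], pd["t3", "t5"], pd["t3", "t9"]))
  expect_equal(min_host_distance(pd, "t1", hosts),
               min(pd["t1", "t5"], pd["t1", "t9"]))
  expect_error(min_host_distance(pd, "t1", "t1"), "no known hosts")
})
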