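# Independent oracles used across the suite: direct-formula and brute-force
# computations kept deliberately separate from the package's own code paths.

# Pearson correlation from the raw covariance/SD definition.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Loop-based windowed error metrics.
oracle_error <- function(truth, fc, metric, window, step) {
  starts <- seq(1, length(truth) - window + 1, by = step)
  sapply(starts, function(s) {
    r <- fc[s:(s + window - 1)] - truth[s:(s + window - 1)]
    switch(metric,
           bias = mean(r), MSE = mean(r^2), RMSE = sqrt(mean(r^2)),
           MAE = mean(abs(r)))
  })
}

# Sort-based type-7 percentile (finite values only).
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
}

# Dense-grid first falls-below crossing of a sampled curve, linearly
# interpolated onto a 1e-4 grid.
oracle_dense_crossing <- function(f, from, to, threshold, dd = 1e-4) {
  g <- seq(from, to, by = dd)
  v <- f(g)
  i <- which(v < threshold)[1]
  if (is.na(i)) return(Inf)
  if (i == 1) return(g[1])
  g[i - 1] + (threshold - v[i - 1]) / (v[i] - v[i - 1]) * dd
}

# Breadth-first path-sum patristic distances over the edge list.
oracle_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  adj <- vector("list", nn)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]; w <- tree$edge.length[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  m <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    dist <- rep(NA_real_, nn); dist[i] <- 0
    queue <- i
    while (length(queue)) {
      nd <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[nd]]))) {
        nb <- adj[[nd]][k, 1]; w <- adj[[nd]][k, 2]
        if (is.na(dist[nb])) {
          dist[nb] <- dist[nd] + w
          queue <- c(queue, nb)
        }
      }
    }
    m[i, ] <- dist[seq_len(ntip)]
  }
  m
}

# Exhaustive positive-negative pair comparison AUC with half-credit ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Small deterministic ensemble fixture.
make_ensemble <- function(n = 30, nrep = 1, seed = 1, fc_fun = identity) {
  set.seed(seed)
  tru <- trajectory(seq_len(n), cumsum(rnorm(n)) + 10)
  fcs <- lapply(seq_len(nrep), function(i) {
    trajectory(tru$times, fc_fun(tru$values))
  })
  forecast_ensemble(tru, fcs)
}
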