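# Independent oracles used across the suite. Each is implemented from first
# principles (enumeration, closed forms, textbook algebra) and never calls
# the package code path it checks.

# Minimum within-group SS over ALL 2-partitions of v (brute force).
# Enumerates every proper bipartition once by keeping the last element in
# group B; vectorized over bit masks.
oracle_min_ss_2part <- local({
  mask_cache <- list()
  function(v) {
    n <- length(v)
    key <- as.character(n)
    if (is.null(mask_cache[[key]])) {
      m <- seq_len(2^(n - 1) - 1)
      M <- matrix(0, length(m), n)
      for (j in seq_len(n - 1)) M[, j] <- bitwAnd(m, 2^(j - 1)) > 0
      mask_cache[[key]] <<- M
    }
    M <- mask_cache[[key]]
    s1 <- as.numeric(M %*% v)
    q1 <- as.numeric(M %*% v^2)
    n1 <- rowSums(M)
    S <- sum(v); Q <- sum(v^2)
    ss <- (q1 - s1^2 / n1) + ((Q - q1) - (S - s1)^2 / (n - n1))
    min(ss)
  }
})

# Exhaustive threshold scan: best specificity achievable at sensitivity >=
# target with the call rule "high risk iff score >= t".
oracle_cutoff_scan <- function(scores, labels, target) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  cand <- sort(unique(c(scores, max(scores) + 1)))
  best <- -Inf
  for (t in cand) {
    sens <- mean(pos >= t)
    if (sens >= target) best <- max(best, mean(neg < t))
  }
  best
}

# Textbook IRLS (Newton-Raphson) for logistic regression with intercept.
oracle_irls <- function(X, y, iters = 50) {
  X <- cbind(1, X)
  b <- rep(0, ncol(X))
  for (i in seq_len(iters)) {
    eta <- as.numeric(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    b <- solve(t(X) %*% (W * X), t(X) %*% (W * z))
  }
  as.numeric(b)
}

# Naive agglomerative average-linkage: merge heights from all-pairs mean
# distances, recomputed from scratch at every step.
oracle_avg_linkage_heights <- function(m) {
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Exact two-sided Mann-Whitney p by enumeration of all label assignments
# (tie-free data), using the 2*min(tail) convention.
oracle_mw_exact_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(n, nx)
  u_null <- apply(combos, 2, u_of)
  p <- 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs))
  min(1, p)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Reduced-scale cohort configurations used by the property suite; sizes are
# chosen so a seeded replicate runs in well under a second.
small_signal_cfg <- function(...) {
  sim_config(n_tumor = 80, n_clusters = 4, probes_per_cluster = 25,
             n_noise_probes = 300, ...)
}

small_null_cfg <- function() {
  sim_config(n_tumor = 80, n_clusters = 4, probes_per_cluster = 15,
             n_noise_probes = 100, cluster_weights = rep(0, 4),
             alpha = qlogis(20 / 78), clinical_group_effects = FALSE)
}

# Full small pipeline -> fitted triple-set model (in-sample).
fit_triple_pipeline <- function(sim, k, seed) {
  fit <- dca_fit(sim$tumors, pipeline_config(k = k, seed = seed))
  clin <- impute_clinical_means(sim$clinical)
  feats <- assemble_features(clin, pi_betas = sim$tumors, consensus = fit$consensus,
                             set_name = "triple", pi_cpg_ids = sim$pi_cpg_ids)
  list(dca = fit, features = feats, model = fit_risk_model(feats, sim$clinical$progress_event))
}

# Split-half null-calibration replicate: unsupervised DCA on everyone,
# logistic fit on the training half, cutoff fixed at 85% sensitivity on the
# held-out half. Returns held-out specificity and the order-statistic
# closed form for the held-out class sizes (NA when a half lacks a class).
null_calibration_rep <- function(seed, target = 0.85) {
  sim <- simulate_cohort(small_null_cfg(), seed = seed)
  fit <- dca_fit(sim$tumors, pipeline_config(k = 4, seed = seed))
  clin <- impute_clinical_means(sim$clinical)
  feats <- assemble_features(clin, pi_betas = sim$tumors, consensus = fit$consensus,
                             set_name = "triple", pi_cpg_ids = sim$pi_cpg_ids)
  y <- sim$clinical$progress_event
  train <- seq_len(nrow(feats)) %% 2 == 0
  if (min(table(y[train])) < 2 || min(table(y[!train])) < 2) {
    return(c(specificity = NA_real_, closed_form = NA_real_))
  }
  m <- fit_risk_model(feats[train, ], y[train])
  p <- predict(m, feats[!train, ])
  cc <- choose_cutoff(p$posterior, y[!train], target)
  np <- sum(y[!train]); k <- ceiling(target * np)
  c(specificity = cc$specificity, closed_form = (np + 1 - k) / (np + 1))
}
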