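# Independent brute-force oracles used to validate the package's
# implementations. Each is written as directly as possible from the
# defining property, with no shared code with the implementation.

# Quadratic run-length scanner: tests every index for a state change.
oracle_rle <- function(mask) {
  n <- length(mask)
  starts <- integer(0)
  for (i in seq_len(n)) {
    if (i == 1L || mask[i] != mask[i - 1L]) starts <- c(starts, i)
  }
  ends <- c(starts[-1L] - 1L, n)
  data.frame(
    start_index = starts - 1L,
    duration = ends - starts + 1L,
    state = ifelse(mask[starts], "sedentary", "active"),
    stringsAsFactors = FALSE
  )
}

# Per-position centred moving median of observed neighbours.
oracle_moving_median <- function(counts, window) {
  n <- length(counts)
  half_lo <- ceiling((window - 1) / 2)
  half_hi <- floor((window - 1) / 2)
  out <- counts
  for (i in which(is.na(counts))) {
    lo <- max(1L, i - half_lo)
    hi <- min(n, i + half_hi)
    vals <- counts[lo:hi]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) {
      obs <- which(!is.na(counts))
      vals <- counts[obs[which.min(abs(obs - i))]]
    }
    out[i] <- median(vals)
  }
  out
}

# Counting definition of the ECDF: fraction of sample values <= x.
oracle_ecdf <- function(sample, x) {
  vapply(x, function(xx) sum(sample <= xx) / length(sample), numeric(1))
}

# Exhaustive permutation distribution of the two-sample K-S statistic for
# continuous (tie-free) data: D depends only on which pooled ranks belong
# to x, so every n1-subset of the pooled sample is enumerated.
oracle_ks_perm_p <- function(n1, n2, d_obs) {
  combos <- combn(n1 + n2, n1)
  n_tot <- ncol(combos)
  ind <- matrix(0, nrow = n1 + n2, ncol = n_tot)
  ind[cbind(as.vector(combos), rep(seq_len(n_tot), each = n1))] <- 1
  cum_x <- ind
  for (i in 2:(n1 + n2)) cum_x[i, ] <- cum_x[i - 1L, ] + ind[i, ]
  pos <- matrix(seq_len(n1 + n2), nrow = n1 + n2, ncol = n_tot)
  gaps <- abs(cum_x / n1 - (pos - cum_x) / n2)
  d_all <- gaps[1L, ]
  for (i in 2:(n1 + n2)) d_all <- pmax(d_all, gaps[i, ])
  mean(d_all >= d_obs - 1e-12)
}

# Renewal-theory long-run occupancy of the sedentary state for the
# minute-discretized generator: E[ceil(Exp(m))] = 1 / (1 - exp(-1/m)).
oracle_occupancy <- function(mean_sed, mean_act) {
  e_ceil <- function(m) 1 / (1 - exp(-1 / m))
  e_ceil(mean_sed) / (e_ceil(mean_sed) + e_ceil(mean_act))
}

# Convenience: simulate a feature matrix and labels from a known logistic
# model, for parameter-recovery checks.
simulate_logistic_data <- function(n, beta, seed = 1) {
  set.seed(seed)
  k <- length(beta) - 1L
  X <- matrix(runif(n * k, 0, 300), nrow = n)
  eta <- beta[1L] + X %*% beta[-1L]
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  list(X = X, y = y)
}

# Fast path from a preset to per-subject all-7 features, bypassing file IO.
features_from_cohort <- function(cohort, config = run_config()) {
  cohort_features(cohort$series, cohort$manifest, config)$features
}

make_series <- function(counts, start = "2024-01-01 08:00", id = "s1",
                        group = "HC") {
  t0 <- as.POSIXct(start, tz = "UTC")
  epoch_series(id, group, t0 + 60 * (seq_along(counts) - 1L), counts)
}
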