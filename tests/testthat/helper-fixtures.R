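# Shared fixtures and independent oracles used across test files.

# A representative sensory-precision table (identification improving with
# vocoder channels).
fixture_s_table <- function() {
  data.frame(channels = c(4, 8, 16), s = c(0.25, 0.55, 0.85))
}

# Independent forward model, written out in plain arithmetic so that fitting
# and prediction code paths are checked against it rather than against
# themselves. Returns the 6 condition-mean ratings (match 4/8/16 then
# mismatch 4/8/16) or NULL when the mapping is degenerate.
oracle_condition_means <- function(sigma, theta, s_table, w_match = 0.5,
                                   w_match_16 = NULL) {
  s <- s_table$s[match(c(4, 8, 16, 4, 8, 16), s_table$channels)]
  w <- c(rep(w_match, 3), rep(0, 3))
  if (!is.null(w_match_16)) w[3] <- w_match_16
  p <- s * (1 + w / sigma^2)
  if (all(p <= theta)) return(NULL)
  p_ref <- max(p)
  pmin(4, pmax(1, 1 + 3 * (p - theta) / (p_ref - theta)))
}

# Brute-force grid search over (log sigma, theta); the independent oracle for
# the multi-start optimiser. Returns the best RSS found on the grid.
oracle_grid_rss <- function(observed, s_table, n_grid = 100) {
  lsig <- seq(log(1e-3), log(1e3), length.out = n_grid)
  thetas <- seq(0, max(s_table$s) * 0.999, length.out = n_grid)
  best <- Inf
  for (ls in lsig) {
    for (th in thetas) {
      pred <- oracle_condition_means(exp(ls), th, s_table)
      if (is.null(pred)) next
      rss <- sum((observed - pred)^2)
      if (rss < best) best <- rss
    }
  }
  best
}

# Full enumeration of the rank-sum null over all labelings of the pooled
# sample: the independent oracle for the exact test.
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Small coupled-and-lagged pair used by several connectivity tests: a common
# 18 Hz component enters region y a quarter cycle later than region x.
fixture_lagged_pair <- function(n_trials = 60, len = 228, fs = 250,
                                f = 18, lag_frac = 0.25, amp = 1,
                                seed = 1) {
  set.seed(seed)
  tt <- (seq_len(len) - 1) / fs
  lag <- lag_frac / f
  x <- matrix(0, n_trials, len)
  y <- matrix(0, n_trials, len)
  for (i in seq_len(n_trials)) {
    ph <- runif(1, 0, 2 * pi)
    x[i, ] <- amp * sin(2 * pi * f * tt + ph) + rnorm(len)
    y[i, ] <- amp * sin(2 * pi * f * (tt - lag) + ph) + rnorm(len)
  }
  list(x = x, y = y, fs = fs)
}
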