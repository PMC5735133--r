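test_that("multitaper spectra use the +/-4 Hz taper count and behave like spectra", {
  set.seed(1)
  x <- matrix(rnorm(40 * 228), 40)
  y <- matrix(rnorm(40 * 228), 40)
  est <- multitaper_cross_spectra(x, y, fs = 250)
  expect_equal(est$n_tapers, 6)   # floor(2 * 0.912 * 4 - 1)
  expect_true(all(est$sxx >= 0) && all(est$syy >= 0))
  # cross-spectrum is conjugate-symmetric in the region order
  est_rev <- multitaper_cross_spectra(y, x, fs = 250)
  expect_equal(est_rev$sxy, Conj(est$sxy), tolerance = 1e-10)
  # white-noise auto-spectrum is flat within sampling error
  pm <- colMeans(est$sxx)
  expect_lt(sd(pm) / mean(pm), 0.2)
  # an 18 Hz sinusoid peaks within the smoothing bandwidth of 18 Hz
  tt <- (0:227) / 250
  xs <- matrix(rep(sin(2 * pi * 18 * tt), 10), 10, byrow = TRUE) +
    matrix(rnorm(10 * 228, sd = 0.1), 10)
  es <- multitaper_cross_spectra(xs, xs + rnorm(228, sd = 0.1), fs = 250)
  expect_lte(abs(es$freqs[which.max(colMeans(es$sxx))] - 18), 4)
})

test_that("imaginary coherence ignores zero-lag coupling but detects lagged coupling", {
  pair0 <- fixture_lagged_pair(lag_frac = 0, amp = 1.5, seed = 2)
  ic0 <- imaginary_coherence(pair0$x, pair0$y, fs = pair0$fs)
  expect_lt(max(ic0), 0.12)       # zero-lag common signal: no imaginary part

  pair <- fixture_lagged_pair(lag_frac = 0.25, amp = 1, seed = 3)
  nul <- permutation_null(pair$x, pair$y, "imaginary_coherence",
                          n_permutations = 200, seed = 1, fs = pair$fs)
  inband <- nul$freqs >= 14 & nul$freqs <= 22
  expect_true(all(nul$exceeds[inband]))

  # independent noise: within null at >= 90% of frequencies
  set.seed(4)
  nul0 <- permutation_null(matrix(rnorm(60 * 228), 60),
                           matrix(rnorm(60 * 228), 60),
                           "imaginary_coherence",
                           n_permutations = 200, seed = 2)
  expect_lte(mean(nul0$exceeds), 0.10)
})

test_that("imaginary coherence is unchanged by adding a zero-lag common signal", {
  set.seed(5)
  x <- matrix(rnorm(60 * 228), 60)
  y <- matrix(rnorm(60 * 228), 60)
  common <- matrix(rnorm(60 * 228), 60)
  ic_plain <- imaginary_coherence(x, y, fs = 250)
  ic_common <- imaginary_coherence(x + common, y + common, fs = 250)
  # stays at sampling-noise level; zero-lag common input adds nothing imaginary
  expect_lt(mean(ic_common), 0.05)
  expect_lt(max(ic_common), 0.15)
  expect_lt(mean(abs(ic_common - ic_plain)), 0.03)
})

test_that("permutation nulls are seeded, sized, and exclude the observed statistic", {
  src <- simulate_coupled_sources(coupling_spec("none"), n_trials = 30, seed = 6)
  n1 <- permutation_null(src, n_permutations = 150, seed = 9)
  n2 <- permutation_null(src, n_permutations = 150, seed = 9)
  expect_identical(n1$quantiles, n2$quantiles)
  expect_equal(nrow(n1$null), 150)
  expect_false(identical(
    n1$quantiles, permutation_null(src, n_permutations = 150, seed = 10)$quantiles))
  expect_warning(permutation_null(src, n_permutations = 50, seed = 1),
                 "permutations")
})

test_that("spectral Granger recovers the implanted direction and stays non-negative", {
  src <- simulate_coupled_sources(coupling_spec("frontal->temporal",
                                                band_hz = c(13, 23)),
                                  n_trials = 80, seed = 7)
  src <- subtract_evoked(src)
  g <- spectral_granger(src, order = 8)
  expect_true(all(g$granger >= 0))
  beta <- g$freqs >= 13 & g$freqs <= 23
  expect_gt(mean(g$granger[beta, "frontal->temporal"]),
            5 * mean(g$granger[beta, "temporal->frontal"]))

  nul <- permutation_null(src, statistic = "granger", n_permutations = 100,
                          seed = 3, order = 8)
  expect_true(mean(nul$exceeds[beta, "frontal->temporal"]) >= 0.8)
  expect_true(mean(nul$exceeds[beta, "temporal->frontal"]) <= 0.2)

  # independent series: both directions within null at >= 90% of frequencies
  # (averaged over source sets; per-set rates are correlated across frequency)
  rates <- vapply(1:3, function(k) {
    src0 <- simulate_coupled_sources(coupling_spec("none"), n_trials = 80,
                                     seed = 30 + k)
    mean(permutation_null(src0, statistic = "granger", n_permutations = 100,
                          seed = 40 + k, order = 8)$exceeds)
  }, numeric(1))
  expect_lte(mean(rates), 0.10)
})

test_that("relative influence normalises each direction to unit mean, scale-free", {
  flat <- matrix(3, 39, 2)
  expect_equal(relative_influence(flat), matrix(1, 39, 2))
  set.seed(9)
  g <- matrix(rexp(39 * 2), 39)
  ri <- relative_influence(g)
  expect_lt(max(abs(colMeans(ri) - 1)), 1e-9)
  expect_equal(relative_influence(7 * g), ri)
  expect_error(relative_influence(matrix(0, 5, 2)), "positive")
})

test_that("directionality contrast finds implanted opposite-band dominance", {
  set.seed(10)
  freqs <- seq(4, 80, 2)
  n_sub <- 10
  lowband <- freqs <= 12; beta <- freqs >= 13 & freqs <= 23
  # frontal->temporal dominates in beta; temporal->frontal at low frequencies
  prof_ft <- matrix(1, n_sub, 39) + matrix(rnorm(n_sub * 39, sd = 0.1), n_sub)
  prof_tf <- prof_ft + matrix(rnorm(n_sub * 39, sd = 0.1), n_sub)
  prof_ft[, beta] <- prof_ft[, beta] + 0.6
  prof_tf[, lowband] <- prof_tf[, lowband] + 0.6
  dc <- directionality_contrast(prof_ft, prof_tf, freqs = freqs,
                                n_permutations = 500, seed = 1)
  sig <- dc$clusters[dc$clusters$p <= dc$alpha, ]
  expect_true(any(sig$sign == 1 & sig$from_hz >= 13 & sig$to_hz <= 23))
  expect_true(any(sig$sign == -1 & sig$to_hz <= 12))
})

test_that("direction-symmetric profiles rarely produce significant clusters", {
  set.seed(11)
  freqs <- seq(4, 80, 2)
  clean <- vapply(1:40, function(i) {
    a <- matrix(rnorm(8 * 39, 1, 0.2), 8)
    b <- matrix(rnorm(8 * 39, 1, 0.2), 8)
    dc <- directionality_contrast(a, b, freqs = freqs,
                                  n_permutations = 300, seed = i)
    !any(dc$sig_mask)
  }, logical(1))
  expect_gte(mean(clean), 0.9)
})

test_that("a single frequency degenerates to a paired t-test", {
  set.seed(12)
  a <- matrix(rnorm(12, 1.5, 0.3), 12, 1)
  b <- matrix(rnorm(12, 1.0, 0.3), 12, 1)
  dc <- directionality_contrast(a, b, n_permutations = 4000, seed = 2)
  tt <- t.test(a[, 1], b[, 1], paired = TRUE)
  expect_equal(unname(dc$t), unname(tt$statistic), tolerance = 1e-10)
  expect_equal(nrow(dc$clusters), 1)
  expect_lt(abs(dc$clusters$p - tt$p.value), 0.03)
  expect_error(directionality_contrast(a[1:2, , drop = FALSE],
                                       b[1:2, , drop = FALSE]), "3 subjects")
})
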