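pool <- sprintf("w%03d", 1:432)
sched1 <- exp1_schedule(pool, seed = 1)
sched2 <- exp2_schedule(make_response_sets(), seed = 1)

test_that("simulated ratings respect the scale, congruency ordering and determinism", {
  p <- perceptual_parameters(0.5, 0.05, rating_noise_sd = 0.3,
                             identification_ability = 1)
  d <- simulate_subject(p, sched1, sched2, seed = 2)
  expect_true(all(d$exp1$rating %in% 1:4))
  expect_true(all(d$exp2$correct %in% 0:1))
  expect_identical(d, simulate_subject(p, sched1, sched2, seed = 2))

  # noiseless, precise prior: match mean >= mismatch mean at every level
  p0 <- perceptual_parameters(0.3, 0.05, rating_noise_sd = 0,
                              identification_ability = 1)
  d0 <- simulate_subject(p0, sched1, sched2, seed = 3)
  for (ch in c(4, 8, 16)) {
    m <- with(d0$exp1, tapply(rating, congruency, mean))
    expect_gte(m[["match"]], m[["mismatch"]])
  }
})

test_that("identification accuracy rises with channels and falls with neighbours", {
  p <- perceptual_parameters(1, 0.05, identification_ability = 0.5)
  big <- sched2[rep(seq_len(nrow(sched2)), 120), ]  # ~3600 trials per channel
  d <- simulate_subject(p, sched1, big, seed = 4)
  acc <- with(d$exp2, tapply(correct, list(channels, n_neighbours_in_array), mean))
  # non-decreasing in channels at fixed difficulty
  for (j in seq_len(ncol(acc))) expect_true(all(diff(acc[, j]) > -0.02))
  # harder with more neighbours at fixed channels
  for (i in seq_len(nrow(acc))) expect_true(all(diff(acc[i, ]) < 0.02))
  # derived sensory-precision table follows the above-chance rescaling
  expect_equal(d$precision$s, sensory_precision(d$precision$accuracy))
})

test_that("cohort defaults give 11 per group, precise-prior patients, larger patient effects", {
  spec <- cohort_spec(seed = 5)
  cohort <- simulate_cohort(spec)
  grp <- vapply(cohort, `[[`, character(1), "group")
  expect_equal(sum(grp == "control"), 11)
  expect_equal(sum(grp == "patient"), 11)
  sig <- vapply(cohort, function(s) s$params$sigma_prior, numeric(1))
  expect_lt(median(sig[grp == "patient"]), median(sig[grp == "control"]))
  eff <- vapply(cohort, function(s) congruency_effect(s$dataset)$overall,
                numeric(1))
  expect_gt(mean(eff[grp == "patient"]), mean(eff[grp == "control"]))
  expect_identical(simulate_cohort(spec)[[3]]$dataset$exp1$rating,
                   cohort[[3]]$dataset$exp1$rating)
})

test_that("coupled sources have the stated geometry and reject zero lag", {
  expect_error(coupling_spec(lag_samples = 0), "lag")
  src <- simulate_coupled_sources(coupling_spec("frontal->temporal"),
                                  n_trials = 20, seed = 6)
  expect_equal(dim(src$frontal), c(20, 228))   # round(0.912 s * 250 Hz)
  expect_equal(dim(src$temporal), dim(src$frontal))
  expect_equal(src$fs, 250)
  # strength 0: receiver is exactly its own noise process
  s0 <- simulate_coupled_sources(coupling_spec("frontal->temporal", strength = 0),
                                 n_trials = 10, seed = 7)
  s_none <- simulate_coupled_sources(coupling_spec("none"), n_trials = 10, seed = 7)
  expect_equal(s0$temporal, s_none$temporal)
})

test_that("implanted time-frequency latencies are recovered to one sample", {
  for (lat in c(300, 500, 900)) {
    maps <- simulate_tf_contrast(lat, seed = 8)
    bc <- band_contrast_latency(maps$match, maps$mismatch)
    expect_true(bc$defined)
    expect_lte(abs(bc$t80_ms - lat), 4)
  }
  # amplitude 0: latency operator reports undefined
  m0 <- simulate_tf_contrast(300, amplitude = 0, seed = 8)
  expect_false(band_contrast_latency(m0$match, m0$mismatch)$defined)
  expect_error(simulate_tf_contrast(1500), "window")
})

test_that("vocoding preserves duration and gains envelope fidelity with channels", {
  fs <- 8000
  tt <- seq(0, 0.5, by = 1 / fs)
  # synthetic harmonic "word": three harmonics under a syllabic envelope
  env <- pmax(0, sin(2 * pi * 3 * tt))
  wav <- env * (sin(2 * pi * 150 * tt) + 0.5 * sin(2 * pi * 450 * tt) +
                  0.25 * sin(2 * pi * 900 * tt))
  out <- vocode(wav, 8, fs = fs, seed = 1)
  expect_equal(length(out), length(wav))
  expect_error(vocode(wav, 0, fs = fs), "n_channels")

  # per-band envelope fidelity: correlation of band envelopes between input
  # and output, averaged over a fixed 12-band analysis filterbank
  band_env_cor <- function(a, b, nb = 12) {
    edges <- exp(seq(log(70), log(5000), length.out = nb + 1))
    f <- (seq_along(a) - 1) * fs / length(a); f <- pmin(f, fs - f)
    bp <- function(x, lo, hi) {
      z <- stats::fft(x); z[!(f >= lo & f < hi)] <- 0
      Re(stats::fft(z, inverse = TRUE)) / length(x)
    }
    lp <- function(x) {
      z <- stats::fft(x); z[f > 30] <- 0
      Re(stats::fft(z, inverse = TRUE)) / length(x)
    }
    cs <- sapply(seq_len(nb), function(k) {
      ea <- lp(pmax(bp(a, edges[k], edges[k + 1]), 0))
      eb <- lp(pmax(bp(b, edges[k], edges[k + 1]), 0))
      if (sd(ea) < 1e-12 || sd(eb) < 1e-12) return(NA_real_)
      cor(ea, eb)
    })
    mean(cs, na.rm = TRUE)
  }
  cors <- sapply(1:20, function(sd) {
    c(band_env_cor(wav, vocode(wav, 4, fs = fs, seed = sd)),
      band_env_cor(wav, vocode(wav, 16, fs = fs, seed = sd)))
  })
  expect_gt(mean(cors[2, ]), mean(cors[1, ]))
})
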