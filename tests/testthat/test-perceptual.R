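s_tab <- fixture_s_table()

test_that("sensory precision rescales accuracy above chance onto [0, 1]", {
  expect_equal(sensory_precision(0.25), 0)
  expect_equal(sensory_precision(1), 1)
  expect_equal(sensory_precision(0.625), 0.5)
  expect_equal(sensory_precision(0.1), 0)   # below-chance floor
  expect_error(sensory_precision(1.2), "\\[0, 1\\]")
})

test_that("posterior precision is multiplicative in the weighted prior and reduces to s at w = 0", {
  expect_equal(posterior_precision(0.6, 2, 0), 0.6)
  expect_equal(posterior_precision(0.5, 1, 0.5), 0.75)
  # uninformative-prior limit
  expect_equal(posterior_precision(0.6, 1e3, 0.5), 0.6, tolerance = 1e-6)
  # monotone in w and in prior precision
  expect_true(posterior_precision(0.5, 1, 0.6) > posterior_precision(0.5, 1, 0.4))
  expect_true(posterior_precision(0.5, 0.5, 0.5) > posterior_precision(0.5, 1, 0.5))
  expect_error(posterior_precision(0.5, 0, 0.5), "positive")
})

test_that("clarity mapping anchors threshold to 1, the reference precision to 4, linear between", {
  expect_equal(predict_clarity(c(0.1, 0.5), threshold = 0.1), c(1, 4))
  p_mid <- 0.1 + 0.5 * (0.5 - 0.1)
  expect_equal(predict_clarity(c(0.1, p_mid, 0.5), threshold = 0.1),
               c(1, 2.5, 4))
  expect_error(predict_clarity(c(0.05, 0.08), threshold = 0.1), "degenerate")
})

test_that("AICc matches its closed form and penalises parameters monotonically", {
  expect_equal(aicc(6, 6, 2), 8)
  expect_equal(aicc(6, 6, 3), 18)
  expect_true(aicc(3, 6, 3) > aicc(3, 6, 2))
  expect_error(aicc(1, 4, 3), "n - k - 1")
})

test_that("variance explained matches independent arithmetic", {
  obs <- c(1, 2, 4); pred <- c(1.5, 2, 3.5)
  # by hand: SS_tot = 1 + 0.1111*... about mean 7/3
  ss_tot <- sum((obs - mean(obs))^2)
  ss_res <- 0.25 + 0 + 0.25
  expect_equal(variance_explained(pred, obs), 100 * (1 - ss_res / ss_tot))
  expect_equal(variance_explained(obs, obs), 100)
  expect_equal(variance_explained(rep(mean(obs), 3), obs), 0)
  expect_error(variance_explained(c(1, 1), c(2, 2)), "zero variance")
})

test_that("noiseless generate-and-refit recovers the generating parameters", {
  truth <- oracle_condition_means(0.8, 0.1, s_tab)
  fit <- fit_clarity(truth, precision = s_tab, seed = 1)
  expect_lt(fit$rss, 1e-6)
  expect_equal(unname(coef(fit)), c(0.8, 0.1), tolerance = 1e-3)
  # model predictions agree with the independent forward arithmetic
  expect_equal(unname(fitted(fit)), truth, tolerance = 1e-4)
})

test_that("identical match and mismatch ratings drive the prior effect to nil", {
  # condition means consistent across congruency: the best fit needs a prior
  # so broad it contributes nothing
  obs <- rep(1 + 3 * (s_tab$s - 0.05) / (0.85 - 0.05), 2)
  fit <- fit_clarity(obs, precision = s_tab, seed = 2)
  expect_gt(coef(fit)[["sigma_prior"]], 100)
  expect_lt(mean(fitted(fit)[1:3] - fitted(fit)[4:6]), 1e-3)
  expect_lt(fit$rss, 1e-6)
})

test_that("multi-start optimiser never loses to a 100 x 100 grid search", {
  set.seed(42)
  for (i in 1:20) {
    sigma <- exp(runif(1, log(0.2), log(3)))
    theta <- runif(1, 0, 0.15)
    obs <- oracle_condition_means(sigma, theta, s_tab) +
      runif(6, -0.2, 0.2)
    obs <- pmin(4, pmax(1, obs))
    fit <- fit_clarity(obs, precision = s_tab, seed = i)
    expect_lte(fit$rss, oracle_grid_rss(obs, s_tab, n_grid = 100) + 1e-9)
  }
})

test_that("refitting on model predictions does not increase the RSS (idempotence)", {
  obs <- oracle_condition_means(0.6, 0.05, s_tab) + c(0.1, -0.1, 0, 0.1, 0, -0.1)
  f1 <- fit_clarity(obs, precision = s_tab, seed = 3)
  f2 <- fit_clarity(unname(fitted(f1)), precision = s_tab, seed = 3)
  expect_lte(f2$rss, f1$rss + 1e-9)
})

test_that("the congruency effect shrinks as the prior broadens", {
  sigmas <- exp(seq(log(0.2), log(5), length.out = 12))
  gaps <- vapply(sigmas, function(sg) {
    m <- oracle_condition_means(sg, 0.05, s_tab)
    mean(m[1:3] - m[4:6])
  }, numeric(1))
  expect_true(all(diff(gaps) <= 1e-10))
})

test_that("with all congruency weights zero the model predicts no congruency effect", {
  m <- priorclarity:::predict_conditions(0.7, 0.05, s_tab, w_match = 0)
  expect_equal(m[1:3], m[4:6])
})

test_that("variant comparison prefers by AICc, breaking ties toward the simple model", {
  truth <- oracle_condition_means(0.8, 0.05, s_tab)
  fs <- fit_clarity(truth, precision = s_tab, variant = "simple", seed = 1)
  fc <- fit_clarity(truth, precision = s_tab, variant = "complex", seed = 1)
  cmp <- compare_variants(fs, fc)
  expect_gte(cmp$delta_aicc, 0)
  # identical AICc -> simple by parsimony
  fc2 <- fc; fc2$aicc <- fs$aicc
  expect_equal(compare_variants(fs, fc2)$winner, "simple")
  # mismatched data rejected
  other <- fit_clarity(pmax(1, truth - 0.3), precision = s_tab, seed = 1)
  expect_error(compare_variants(other, fc), "different observed data")
})

test_that("a strong distinct 16-channel match weighting is detected by the complex variant", {
  set.seed(7)
  wins <- vapply(1:12, function(i) {
    obs <- oracle_condition_means(0.8, 0.05, s_tab, w_match_16 = 0.02) +
      rnorm(6, 0, 0.05)
    obs <- pmin(4, pmax(1, obs))
    fs <- fit_clarity(obs, precision = s_tab, variant = "simple", seed = i)
    fc <- fit_clarity(obs, precision = s_tab, variant = "complex", seed = i)
    compare_variants(fs, fc)$winner
  }, character(1))
  expect_gt(mean(wins == "complex"), 0.5)
})

test_that("clarity_fit methods are coherent (predict, residuals, simulate, summary)", {
  obs <- oracle_condition_means(0.7, 0.08, s_tab) + c(0.05, 0, -0.05, 0, 0.05, 0)
  fit <- fit_clarity(obs, precision = s_tab, seed = 4)
  expect_equal(unname(predict(fit)), unname(fitted(fit)))
  nd <- data.frame(congruency = "match", channels = 8)
  expect_equal(unname(predict(fit, nd)), unname(fitted(fit))[2])
  expect_equal(unname(residuals(fit)), obs - unname(fitted(fit)))
  sim <- simulate(fit, seed = 1, n_per_condition = 10)[[1]]
  expect_true(all(sim$rating %in% 1:4))
  expect_equal(nrow(sim), 60)
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("Condition means", out)))
})
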