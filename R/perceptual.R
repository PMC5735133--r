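#' Sensory precision from identification accuracy
#'
#' Converts a listener's word-identification accuracy at a given number of
#' vocoder channels into a sensory-precision value on \[0, 1\]: the proportion
#' correct above chance, rescaled so that chance performance maps to 0 and
#' perfect identification to 1. Accuracy below chance is floored at 0.
#'
#' @param accuracy Proportion correct in \[0, 1\]. Vectorised.
#' @param chance Chance level of the identification task; 0.25 for the
#'   four-alternative forced choice used here.
#' @return Sensory precision in \[0, 1\], same length as `accuracy`.
#' @examples
#' sensory_precision(c(0.25, 0.625, 1))
#' @export
sensory_precision <- function(accuracy, chance = 0.25) {
  if (any(!is.finite(accuracy)) || any(accuracy < 0) || any(accuracy > 1))
    stop("`accuracy` must lie in [0, 1]")
  pmax(0, (accuracy - chance) / (1 - chance))
}

#' Posterior precision of the combined percept
#'
#' The precision of the posterior percept is the precision of the sensory
#' input multiplied by a weighted function of the precision of the prior
#' expectation: `s * (1 + w / sigma_prior^2)`. With weighting `w = 0`
#' (mismatching or uninformative cues) the posterior precision equals the
#' sensory precision; with `w > 0` it grows with the precision
#' `1 / sigma_prior^2` of the prior.
#'
#' @param s Sensory precision (non-negative). Vectorised.
#' @param sigma_prior Standard deviation of the prior expectation (> 0).
#' @param w Congruency weighting in \[0, 1\] (0.5 for matching cues in a
#'   half-congruent context, 0 for mismatching or neutral cues).
#' @return Posterior precision, non-negative.
#' @examples
#' posterior_precision(0.6, sigma_prior = 2, w = 0)    # = 0.6
#' posterior_precision(0.5, sigma_prior = 1, w = 0.5)  # = 0.75
#' @export
posterior_precision <- function(s, sigma_prior, w) {
  if (any(!is.finite(sigma_prior)) || any(sigma_prior <= 0))
    stop("`sigma_prior` must be positive")
  if (any(s < 0)) stop("`s` must be non-negative")
  if (any(w < 0) || any(w > 1)) stop("`w` must lie in [0, 1]")
  s * (1 + w / sigma_prior^2)
}

#' Map posterior precisions to predicted clarity ratings
#'
#' Posterior precision is compared against a perceptual threshold `threshold`:
#' at or below it, degraded speech is deemed completely unclear and rated 1.
#' Above it, the height above threshold is mapped linearly onto the rest of
#' the 1-4 rating scale, anchored so that the listener's maximum condition
#' precision (`p_ref`, defaulting to `max(precisions)`) receives a rating
#' of 4 - implementing instructed use of the full rating range.
#'
#' @param precisions Posterior precision per condition (non-negative vector).
#' @param threshold Perceptual threshold (non-negative scalar).
#' @param p_ref Reference precision anchoring the top of the scale; defaults
#'   to `max(precisions)`.
#' @return Predicted mean ratings in \[1, 4\], one per condition.
#' @export
predict_clarity <- function(precisions, threshold, p_ref = max(precisions)) {
  if (threshold < 0) stop("`threshold` must be non-negative")
  if (all(precisions <= threshold))
    stop("degenerate mapping: every posterior precision is at or below the perceptual threshold")
  if (p_ref <= threshold)
    stop("`p_ref` must exceed `threshold`")
  r <- 1 + 3 * (precisions - threshold) / (p_ref - threshold)
  pmin(4, pmax(1, r))
}

#' Small-sample corrected Akaike information criterion
#'
#' RSS-based AICc: `n * log(rss / n) + 2k + 2k(k + 1)/(n - k - 1)`. Lower is
#' better; the correction term penalises parameters heavily when the number
#' of fitted points is small (here, six condition means).
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of fitted data points.
#' @param k Number of free parameters.
#' @return AICc value.
#' @examples
#' aicc(6, 6, 2)  # 8
#' aicc(6, 6, 3)  # 18
#' @export
aicc <- function(rss, n, k) {
  if (n - k - 1 < 1) stop("AICc undefined: need n - k - 1 >= 1")
  if (rss <= 0) stop("`rss` must be positive")
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Percentage of variance explained
#'
#' `100 * (1 - SS_res / SS_tot)` about the observed mean.
#'
#' @param predicted,observed Equal-length numeric vectors; `observed` must
#'   not be constant.
#' @return Percentage (can be negative for fits worse than the mean).
#' @export
variance_explained <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("`predicted` and `observed` must have equal length")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("`observed` has zero variance")
  100 * (1 - sum((observed - predicted)^2) / ss_tot)
}

## The six Exp1 conditions in canonical order.
condition_grid <- function() {
  data.frame(
    congruency = rep(c("match", "mismatch"), each = 3L),
    channels   = rep(c(4L, 8L, 16L), 2L),
    stringsAsFactors = FALSE
  )
}

## Predicted condition-mean ratings for one parameter set.
## s_table: data.frame(channels, s). Returns vector aligned to condition_grid(),
## or NULL if the mapping is degenerate (all precisions <= threshold).
predict_conditions <- function(sigma_prior, threshold, s_table,
                               w_match = 0.5, w_match_16 = NULL) {
  grid <- condition_grid()
  s <- s_table$s[match(grid$channels, s_table$channels)]
  w <- ifelse(grid$congruency == "match", w_match, 0)
  if (!is.null(w_match_16))
    w[grid$congruency == "match" & grid$channels == 16L] <- w_match_16
  p <- posterior_precision(s, sigma_prior, w)
  if (all(p <= threshold)) return(NULL)
  p_ref <- max(p)
  if (p_ref <= threshold) return(NULL)
  pmin(4, pmax(1, 1 + 3 * (p - threshold) / (p_ref - threshold)))
}

## Condition-mean ratings from a per-trial Exp1 table, in canonical order.
condition_means <- function(exp1) {
  grid <- condition_grid()
  vapply(seq_len(nrow(grid)), function(i) {
    sel <- exp1$congruency == grid$congruency[i] & exp1$channels == grid$channels[i]
    if (!any(sel)) stop("missing condition cell: ", grid$congruency[i], "/", grid$channels[i])
    mean(exp1$rating[sel])
  }, numeric(1))
}

#' Fit the Bayesian clarity model to one listener
#'
#' Estimates the standard deviation of the prior expectation (`sigma_prior`)
#' and the perceptual threshold (`threshold`) by global minimisation of
#' squared residuals between observed and model-predicted condition-mean
#' clarity ratings, over the six cells of the 2 (match/mismatch) x 3
#' (4/8/16 vocoder channels) design. The global strategy is a seeded
#' multi-start bounded quasi-Newton search (Latin-hypercube starting points,
#' `sigma_prior` searched on a log scale), which makes refits reproducible.
#'
#' The `"complex"` variant additionally frees the congruency weighting of
#' matching cues for 16-channel speech (`w_match_16`), emulating a flattening
#' psychometric function at high sensory detail; the two variants are
#' compared by small-sample AICc (see [compare_variants()]).
#'
#' @param data Either a per-trial data frame with columns `congruency`
#'   (`"match"`/`"mismatch"`), `channels` (4/8/16) and `rating` (1-4), or a
#'   length-6 numeric vector of condition-mean ratings ordered as
#'   match 4/8/16 then mismatch 4/8/16. A `subject_dataset` (from
#'   [simulate_subject()]) may also be given, in which case `precision` is
#'   taken from it unless supplied.
#' @param precision Sensory-precision table: data frame with columns
#'   `channels` and `s` (see [sensory_precision()]).
#' @param variant `"simple"` (2 parameters) or `"complex"` (3 parameters).
#' @param w_match Congruency weighting of matching cues (0.5: half the cues
#'   in the experiment matched).
#' @param n_starts Number of Latin-hypercube starting points (>= 32 gives
#'   global-search behaviour on this 2-3 dimensional surface).
#' @param bounds List with elements `sigma_prior` (length-2, positive) and
#'   `threshold` (length-2) giving box constraints.
#' @param seed Integer seed for the start points.
#' @return An object of class `"clarity_fit"`: a list with components
#'   `coefficients` (named vector: `sigma_prior`, `threshold`, and
#'   `w_match_16` for the complex variant), `fitted.values`, `residuals`,
#'   `observed`, `rss`, `aicc`, `variance_explained` (percent), `variant`,
#'   `n_points`, `k`, `precision`, `w_match`, `boundary` (flag: solution at a
#'   box constraint), `data_hash`, and `call`.
#' @seealso [compare_variants()], [predict.clarity_fit()],
#'   [simulate.clarity_fit()]
#' @examples
#' s_tab <- data.frame(channels = c(4, 8, 16), s = c(0.25, 0.55, 0.85))
#' truth <- predict_clarity(
#'   posterior_precision(rep(s_tab$s, 2), 0.8,
#'                       rep(c(0.5, 0), each = 3)), 0.1)
#' fit <- fit_clarity(truth, precision = s_tab, seed = 1)
#' coef(fit)
#' @export
fit_clarity <- function(data, precision = NULL,
                        variant = c("simple", "complex"),
                        w_match = 0.5, n_starts = 32L,
                        bounds = list(sigma_prior = c(1e-3, 1e3),
                                      threshold = NULL),
                        seed = 1L) {
  variant <- match.arg(variant)
  cl <- match.call()

  if (inherits(data, "subject_dataset")) {
    if (is.null(precision)) precision <- data$precision
    data <- data$exp1
  }
  observed <- if (is.numeric(data) && is.null(dim(data))) {
    if (length(data) != 6L) stop("condition-mean vector must have length 6")
    as.numeric(data)
  } else {
    condition_means(as.data.frame(data))
  }
  if (any(observed < 1) || any(observed > 4))
    stop("observed condition means must lie in [1, 4]")
  if (is.null(precision)) stop("a sensory-precision table is required")
  precision <- as.data.frame(precision)
  if (!all(c(4, 8, 16) %in% precision$channels))
    stop("`precision` must cover channels 4, 8 and 16")
  if (!"s" %in% names(precision))
    stop("`precision` must have a column `s`")

  degenerate <- stats::var(observed) == 0
  if (degenerate)
    warning("observed condition means have zero variance; fit will sit on a boundary")

  s_max <- max(precision$s)
  if (s_max <= 0) stop("all sensory precisions are zero; nothing to fit")
  lsig_lo <- log(bounds$sigma_prior[1]); lsig_hi <- log(bounds$sigma_prior[2])
  th_hi <- if (is.null(bounds$threshold)) 0.999 * s_max else bounds$threshold[2]
  th_lo <- if (is.null(bounds$threshold)) 0 else bounds$threshold[1]

  k <- if (variant == "complex") 3L else 2L
  obj <- function(par) {
    sigma <- exp(par[1]); th <- par[2]
    w16 <- if (k == 3L) par[3] else NULL
    pred <- predict_conditions(sigma, th, precision, w_match, w16)
    if (is.null(pred)) return(1e6 + th)        # degenerate all-unclear mapping
    sum((observed - pred)^2)
  }

  lower <- c(lsig_lo, th_lo); upper <- c(lsig_hi, th_hi)
  if (k == 3L) { lower <- c(lower, 0); upper <- c(upper, 1) }

  starts <- with_seed(seed, {
    u <- lhs::randomLHS(as.integer(n_starts), k)
    sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
  })
  # deterministic anchors: mid-box and the default-weighting corner
  anchors <- rbind((lower + upper) / 2,
                   c(log(1), min(0.05, th_hi), if (k == 3L) w_match else NULL))
  starts <- rbind(starts, anchors)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("optimisation failed from every starting point")

  par <- best$par
  coefs <- c(sigma_prior = exp(par[1]), threshold = par[2])
  if (k == 3L) coefs <- c(coefs, w_match_16 = par[3])
  fitted <- predict_conditions(coefs[["sigma_prior"]], coefs[["threshold"]],
                               precision, w_match,
                               if (k == 3L) coefs[["w_match_16"]] else NULL)
  if (is.null(fitted)) stop("fitted parameters give a degenerate mapping")
  rss <- sum((observed - fitted)^2)
  tol <- 1e-6
  boundary <- par[1] <= lsig_lo + tol || par[1] >= lsig_hi - tol ||
    par[2] <= th_lo + tol || par[2] >= th_hi - tol
  ve <- if (degenerate) NA_real_ else variance_explained(fitted, observed)

  structure(list(
    coefficients = coefs,
    fitted.values = fitted,
    residuals = observed - fitted,
    observed = observed,
    rss = rss,
    n_points = 6L,
    k = k,
    aicc = aicc(max(rss, 1e-300), 6L, k),
    variance_explained = ve,
    variant = variant,
    precision = precision[order(precision$channels), c("channels", "s")],
    w_match = w_match,
    boundary = boundary,
    data_hash = hash_numeric(observed),
    call = cl
  ), class = "clarity_fit")
}

## Stable content hash of a numeric vector (used to pair variant fits).
hash_numeric <- function(x) {
  paste(format(x, digits = 15), collapse = "|")
}

#' Compare the simple and complex model variants by AICc
#'
#' Both fits must be to the same observed condition means. The winner is the
#' variant with the lower AICc; ties break toward the simpler model
#' (parsimony).
#'
#' @param fit_simple,fit_complex `clarity_fit` objects of the respective
#'   variants.
#' @return A list of class `"clarity_variant_comparison"` with `winner`
#'   (`"simple"` or `"complex"`), `delta_aicc` (loser minus winner, >= 0),
#'   and the two AICc values.
#' @export
compare_variants <- function(fit_simple, fit_complex) {
  stopifnot(inherits(fit_simple, "clarity_fit"),
            inherits(fit_complex, "clarity_fit"))
  if (fit_simple$variant != "simple" || fit_complex$variant != "complex")
    stop("arguments must be a simple and a complex fit, in that order")
  if (fit_simple$data_hash != fit_complex$data_hash)
    stop("fits were made to different observed data")
  a_s <- fit_simple$aicc; a_c <- fit_complex$aicc
  winner <- if (a_c < a_s) "complex" else "simple"   # tie -> simple
  structure(list(
    winner = winner,
    delta_aicc = abs(a_s - a_c),
    aicc_simple = a_s,
    aicc_complex = a_c
  ), class = "clarity_variant_comparison")
}

#' @export
print.clarity_variant_comparison <- function(x, ...) {
  cat("Model comparison (AICc, corrected for small samples)\n")
  cat(sprintf("  simple : %.3f\n  complex: %.3f\n", x$aicc_simple, x$aicc_complex))
  cat(sprintf("  preferred: %s (delta AICc = %.3f)\n", x$winner, x$delta_aicc))
  invisible(x)
}

#' @export
print.clarity_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Bayesian clarity model (%s variant)\n", x$variant))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("RSS %.4g on 6 condition means; AICc %.3f", x$rss, x$aicc))
  if (!is.na(x$variance_explained))
    cat(sprintf("; variance explained %.1f%%", x$variance_explained))
  cat("\n")
  if (x$boundary) cat("Note: solution lies on a parameter bound\n")
  invisible(x)
}

#' @export
summary.clarity_fit <- function(object, ...) {
  grid <- condition_grid()
  tab <- cbind(grid,
               observed = object$observed,
               fitted = object$fitted.values,
               residual = object$residuals)
  structure(list(fit = object, table = tab), class = "summary.clarity_fit")
}

#' @export
print.summary.clarity_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nCondition means:\n")
  tab <- x$table
  tab[, 3:5] <- round(tab[, 3:5], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.clarity_fit <- function(object, ...) object$coefficients

#' @export
fitted.clarity_fit <- function(object, ...) {
  stats::setNames(object$fitted.values,
                  with(condition_grid(), paste(congruency, channels, sep = "_")))
}

#' @export
residuals.clarity_fit <- function(object, ...) {
  stats::setNames(object$residuals,
                  with(condition_grid(), paste(congruency, channels, sep = "_")))
}

#' Predict mean clarity ratings from a fitted model
#'
#' @param object A `clarity_fit`.
#' @param newdata Optional data frame with columns `congruency` and
#'   `channels`; defaults to the six design cells. The rating-scale anchor
#'   (the listener's maximum condition precision) is always taken from the
#'   fitted design, so predictions for subsets stay on the fitted scale.
#' @param ... Unused.
#' @return Predicted mean ratings in \[1, 4\].
#' @export
predict.clarity_fit <- function(object, newdata = NULL, ...) {
  co <- object$coefficients
  w16 <- if (object$k == 3L) co[["w_match_16"]] else NULL
  grid <- condition_grid()
  s_all <- object$precision$s[match(grid$channels, object$precision$channels)]
  w_all <- ifelse(grid$congruency == "match", object$w_match, 0)
  if (!is.null(w16)) w_all[grid$congruency == "match" & grid$channels == 16L] <- w16
  p_all <- posterior_precision(s_all, co[["sigma_prior"]], w_all)
  p_ref <- max(p_all)
  if (is.null(newdata)) return(predict_clarity(p_all, co[["threshold"]], p_ref))
  newdata <- as.data.frame(newdata)
  idx <- match(paste(newdata$congruency, newdata$channels),
               paste(grid$congruency, grid$channels))
  if (anyNA(idx)) stop("`newdata` rows must be cells of the 2 x 3 design")
  predict_clarity(p_all[idx], co[["threshold"]], p_ref)
}

#' Simulate clarity ratings from a fitted model
#'
#' Draws per-trial ratings at the fitted parameters: the predicted condition
#' mean plus Gaussian rating noise, rounded half-up and clipped to 1-4.
#'
#' @param object A `clarity_fit`.
#' @param nsim Number of simulated datasets.
#' @param seed Integer seed.
#' @param n_per_condition Trials per condition cell (108 in the full design).
#' @param rating_noise_sd Trial-level rating noise SD.
#' @param ... Unused.
#' @return A list of `nsim` data frames with columns `congruency`,
#'   `channels`, `rating`.
#' @export
simulate.clarity_fit <- function(object, nsim = 1, seed = NULL,
                                 n_per_condition = 108L,
                                 rating_noise_sd = 0.3, ...) {
  mu <- predict(object)
  grid <- condition_grid()
  draw_one <- function() {
    rows <- grid[rep(seq_len(6L), each = n_per_condition), ]
    m <- rep(mu, each = n_per_condition)
    r <- round_half_up(m + stats::rnorm(length(m), 0, rating_noise_sd))
    rows$rating <- pmin(4, pmax(1, r))
    rownames(rows) <- NULL
    rows
  }
  if (!is.null(seed)) {
    with_seed(seed, replicate(nsim, draw_one(), simplify = FALSE))
  } else {
    replicate(nsim, draw_one(), simplify = FALSE)
  }
}

#' Plot observed against fitted condition means
#'
#' Observed condition-mean clarity ratings (points) and model predictions
#' (lines) against vocoder channel number, one line per congruency.
#'
#' @param x A `clarity_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.clarity_fit <- function(x, ...) {
  ch <- c(4, 8, 16)
  obs <- matrix(x$observed, 3); fit <- matrix(x$fitted.values, 3)
  graphics::matplot(ch, fit, type = "l", lty = 1, lwd = 2, col = c(4, 2),
                    log = "x", xlab = "Vocoder channels",
                    ylab = "Mean clarity rating", ylim = c(1, 4), ...)
  graphics::matpoints(ch, obs, pch = 19, col = c(4, 2))
  graphics::legend("topleft", c("match", "mismatch"), col = c(4, 2),
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}
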