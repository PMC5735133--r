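## Discrete prolate spheroidal (Slepian) tapers, computed from the standard
## symmetric tridiagonal commuting matrix; W is the half-bandwidth in cycles
## per sample. Returns an N x K matrix of unit-energy tapers.
dpss_tapers <- function(n, k, w) {
  t0 <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  off <- t0[-1] * (n - t0[-1]) / 2
  m <- diag(diag_main)
  m[cbind(1:(n - 1), 2:n)] <- off
  m[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(m, symmetric = TRUE)
  h <- e$vectors[, seq_len(k), drop = FALSE]
  sweep(h, 2, sqrt(colSums(h^2)), `/`)
}

resolve_regions <- function(x, y) {
  if (inherits(x, "source_trials")) {
    list(x = x$frontal, y = x$temporal, fs = x$fs,
         labels = c("frontal", "temporal"))
  } else {
    if (is.null(y)) stop("two trial matrices (or a source_trials object) are required")
    list(x = as.matrix(x), y = as.matrix(y), fs = NULL, labels = c("x", "y"))
  }
}

#' Multitaper cross-spectra of a two-region trial set
#'
#' Slepian-tapered Fourier cross-spectra of evoked-subtracted trials over
#' the analysis window, with `n_tapers = max(1, floor(2 * T * W - 1))` for
#' window length `T` seconds and half-bandwidth `W = 4` Hz (a +/- 4 Hz
#' smoothing box). Per-trial taper-averaged auto- and cross-spectra are
#' retained so that trial-shuffle permutation nulls can be built cheaply.
#'
#' @param x Trials x samples matrix for the first region, or a
#'   `source_trials` object (then `y` and `fs` are taken from it).
#' @param y Trials x samples matrix for the second region.
#' @param fs Sampling rate, Hz.
#' @param bandwidth Half-bandwidth of the spectral smoothing, Hz.
#' @return A list of class `"spectral_estimate"`: `freqs` (Hz, excluding
#'   DC, up to Nyquist), `sxx`, `syy` (trials x freq real), `sxy`
#'   (complex), taper-resolved Fourier coefficients `coef_x`, `coef_y`
#'   ((trials*tapers) x freq complex, with `trial_of_row`), `n_tapers`,
#'   `bandwidth`, `fs`, `n_trials`, `labels`.
#' @export
multitaper_cross_spectra <- function(x, y = NULL, fs = 250, bandwidth = 4) {
  r <- resolve_regions(x, y)
  if (!is.null(r$fs)) fs <- r$fs
  x <- r$x; y <- r$y
  if (!all(dim(x) == dim(y))) stop("regions must have identical trial dimensions")
  n <- ncol(x); n_tr <- nrow(x)
  if (n_tr < 2) stop("at least 2 trials are required")
  tt <- n / fs
  if (tt * bandwidth < 1)
    stop("analysis window too short for the requested bandwidth")
  k <- max(1L, floor(2 * tt * bandwidth - 1))
  h <- dpss_tapers(n, k, bandwidth / fs)

  keep <- 2:(floor(n / 2) + 1)          # drop DC, keep up to Nyquist
  freqs <- (keep - 1) * fs / n
  taper_fft <- function(tr) {
    tr <- sweep(tr, 1, rowMeans(tr))    # demean each trial
    out <- matrix(0i, n_tr * k, length(keep))
    for (j in seq_len(k)) {
      tapered <- sweep(tr, 2, h[, j], `*`)
      ft <- t(apply(tapered, 1, stats::fft))
      out[(j - 1) * n_tr + seq_len(n_tr), ] <- ft[, keep, drop = FALSE]
    }
    out
  }
  cx <- taper_fft(x); cy <- taper_fft(y)
  trial_of_row <- rep(seq_len(n_tr), times = k)

  avg_by_trial <- function(m) {
    out <- matrix(0, n_tr, ncol(m))
    mode(out) <- if (is.complex(m)) "complex" else "numeric"
    for (j in seq_len(k))
      out <- out + m[(j - 1) * n_tr + seq_len(n_tr), , drop = FALSE]
    out / k
  }
  structure(list(
    freqs = freqs,
    sxx = Re(avg_by_trial(cx * Conj(cx))),
    syy = Re(avg_by_trial(cy * Conj(cy))),
    sxy = avg_by_trial(cx * Conj(cy)),
    coef_x = cx, coef_y = cy, trial_of_row = trial_of_row,
    n_tapers = k, bandwidth = bandwidth, fs = fs, n_trials = n_tr,
    labels = r$labels
  ), class = "spectral_estimate")
}

#' Imaginary coherence between two regions
#'
#' The magnitude of the imaginary part of the spectral coherency,
#' `|Im(Sxy / sqrt(Sxx * Syy))|`, from trial-and-taper-averaged spectra.
#' Zero-lag (volume-conducted) coupling contributes only to the real part,
#' so this measure is immune to it.
#'
#' @param est A `"spectral_estimate"` from [multitaper_cross_spectra()], or
#'   a trials x samples matrix together with `y` (and `fs`).
#' @param ... Passed to [multitaper_cross_spectra()] when raw trials are
#'   given.
#' @return Named numeric vector of per-frequency values in \[0, 1\].
#' @export
imaginary_coherence <- function(est, ...) {
  if (!inherits(est, "spectral_estimate"))
    est <- multitaper_cross_spectra(est, ...)
  sxx <- colMeans(est$sxx); syy <- colMeans(est$syy)
  if (any(sxx <= 0) || any(syy <= 0)) stop("zero auto-spectrum")
  sxy <- colMeans(est$sxy)
  stats::setNames(abs(Im(sxy / sqrt(sxx * syy))), format(est$freqs))
}

## Imaginary coherence with region-x trials re-ordered by `perm`
## (fast path over stored taper coefficients).
imag_coh_permuted <- function(est, perm) {
  idx <- rep((perm - 1L), times = est$n_tapers) +
    rep((seq_len(est$n_tapers) - 1L) * est$n_trials, each = est$n_trials) + 1L
  cx <- est$coef_x[idx, , drop = FALSE]
  sxy <- colMeans(cx * Conj(est$coef_y))
  sxx <- colMeans(Re(est$coef_x * Conj(est$coef_x)))
  syy <- colMeans(Re(est$coef_y * Conj(est$coef_y)))
  abs(Im(sxy / sqrt(sxx * syy)))
}

#' Trial-shuffle permutation null for a paired-region statistic
#'
#' Breaks the trial pairing between the two regions by independently
#' permuting one region's trial order in each of `n_permutations`
#' replicates and recomputing the statistic, yielding a per-frequency null
#' ensemble and its 95th percentiles. The observed (unshuffled) statistic
#' is returned separately and is never part of the null ensemble.
#'
#' @param x,y Trials x samples matrices (or `x` a `source_trials` object).
#' @param statistic `"imaginary_coherence"` (fast path), `"granger"`, or a
#'   function `f(x_trials, y_trials, fs)` returning a numeric vector or
#'   matrix of per-frequency values.
#' @param n_permutations Number of shuffles (1000 in the reference
#'   procedure; fewer than 100 triggers a warning).
#' @param seed Integer seed.
#' @param fs Sampling rate, Hz.
#' @param prob Quantile level summarising the null (default 0.95).
#' @param ... Passed to the statistic (e.g. `max_order` for Granger).
#' @return A list of class `"permutation_null"`: `observed`, `quantiles`
#'   (per frequency, same shape as `observed`), `null` (ensemble array with
#'   replicates in the first dimension), `exceeds` (logical,
#'   observed > quantile), `n_permutations`, `prob`, `freqs`.
#' @export
permutation_null <- function(x, y = NULL, statistic = "imaginary_coherence",
                             n_permutations = 1000L, seed = 1L, fs = 250,
                             prob = 0.95, ...) {
  if (n_permutations < 100)
    warning("fewer than 100 permutations gives unstable null quantiles")
  r <- resolve_regions(x, y)
  if (!is.null(r$fs)) fs <- r$fs
  xm <- r$x; ym <- r$y
  n_tr <- nrow(xm)

  if (identical(statistic, "imaginary_coherence")) {
    est <- multitaper_cross_spectra(xm, ym, fs = fs, ...)
    observed <- imaginary_coherence(est)
    freqs <- est$freqs
    null <- with_seed(seed, {
      t(vapply(seq_len(n_permutations), function(i)
        imag_coh_permuted(est, sample.int(n_tr)), numeric(length(freqs))))
    })
  } else {
    stat_fn <- if (identical(statistic, "granger")) {
      function(a, b, fs, ...) {
        g <- spectral_granger(a, b, fs = fs, ...)
        g$granger
      }
    } else statistic
    obs <- stat_fn(xm, ym, fs = fs, ...)
    if (identical(statistic, "granger") && is.matrix(obs))
      colnames(obs) <- c(paste0(r$labels[1], "->", r$labels[2]),
                         paste0(r$labels[2], "->", r$labels[1]))
    observed <- obs
    freqs <- if (!is.null(attr(obs, "freqs"))) attr(obs, "freqs") else
      if (is.matrix(obs)) as.numeric(rownames(obs)) else seq_along(obs)
    null <- with_seed(seed, {
      reps <- lapply(seq_len(n_permutations), function(i)
        as.numeric(stat_fn(xm[sample.int(n_tr), , drop = FALSE], ym, fs = fs, ...)))
      do.call(rbind, reps)
    })
  }
  obs_vec <- as.numeric(observed)
  q <- apply(null, 2, stats::quantile, probs = prob, names = FALSE)
  qs <- obs_vec; qs[] <- q
  ex <- obs_vec > q
  if (is.matrix(observed)) {
    qs <- matrix(qs, nrow(observed), dimnames = dimnames(observed))
    ex <- matrix(ex, nrow(observed), dimnames = dimnames(observed))
  } else {
    names(qs) <- names(observed); names(ex) <- names(observed)
  }
  structure(list(observed = observed, quantiles = qs, null = null,
                 exceeds = ex, n_permutations = n_permutations,
                 prob = prob, freqs = freqs),
            class = "permutation_null")
}

#' Spectral Granger causality between two regions
#'
#' Fits a bivariate vector autoregression by pooled least squares across
#' residual (evoked-subtracted) trials, with the model order chosen by AIC
#' up to `max_order`, then decomposes directed influence over frequency by
#' the Geweke spectral measure
#' `F_{y->x}(f) = ln( Sxx(f) / (Sxx(f) - (S2|1) |Hxy(f)|^2) )`, where `H`
#' is the VAR transfer function and `S2|1` the partialised innovation
#' variance. Unstable fits (companion roots on or outside the unit circle)
#' are rejected.
#'
#' @param x,y Trials x samples matrices (or `x` a `source_trials` object,
#'   in which case directions are labelled frontal/temporal).
#' @param fs Sampling rate, Hz.
#' @param max_order Maximum VAR order considered.
#' @param order Fixed VAR order (skips selection).
#' @param freqs Frequency grid for the decomposition, Hz.
#' @return A list of class `"spectral_granger"`: `freqs`, `granger`
#'   (freq x 2 matrix, columns `<x>-><y>` and `<y>-><x>`), `order`,
#'   `sigma` (innovation covariance), `aic` (per candidate order).
#' @export
spectral_granger <- function(x, y = NULL, fs = 250, max_order = 12L,
                             order = NULL, freqs = seq(4, 80, by = 2)) {
  r <- resolve_regions(x, y)
  if (!is.null(r$fs)) fs <- r$fs
  xm <- r$x; ym <- r$y
  n <- ncol(xm); n_tr <- nrow(xm)
  xm <- sweep(xm, 1, rowMeans(xm)); ym <- sweep(ym, 1, rowMeans(ym))

  build <- function(p) {
    resp <- NULL; pred <- NULL
    rows_per <- n - p
    resp <- matrix(0, n_tr * rows_per, 2)
    pred <- matrix(0, n_tr * rows_per, 2 * p)
    for (i in seq_len(n_tr)) {
      rr <- (i - 1) * rows_per + seq_len(rows_per)
      resp[rr, ] <- cbind(xm[i, (p + 1):n], ym[i, (p + 1):n])
      for (l in seq_len(p))
        pred[rr, (2 * l - 1):(2 * l)] <-
          cbind(xm[i, (p + 1 - l):(n - l)], ym[i, (p + 1 - l):(n - l)])
    }
    list(resp = resp, pred = pred)
  }
  fit_order <- function(p) {
    d <- build(p)
    b <- tryCatch(qr.solve(d$pred, d$resp), error = function(e) NULL)
    if (is.null(b)) return(NULL)
    res <- d$resp - d$pred %*% b
    m <- nrow(d$resp)
    sigma <- crossprod(res) / m
    list(p = p, coef = b, sigma = sigma,
         aic = m * determinant(sigma)$modulus[1] + 2 * (4 * p))
  }

  if (is.null(order)) {
    cand <- lapply(seq_len(max_order), fit_order)
    cand <- Filter(Negate(is.null), cand)
    if (!length(cand)) stop("VAR estimation failed at every order")
    aics <- vapply(cand, `[[`, numeric(1), "aic")
    fit <- cand[[which.min(aics)]]
  } else {
    fit <- fit_order(as.integer(order))
    if (is.null(fit)) stop("VAR estimation failed at the requested order")
    aics <- fit$aic
  }
  p <- fit$p
  # A_l matrices: coef rows are (x_{t-l}, y_{t-l}) pairs, columns (x_t, y_t)
  a_list <- lapply(seq_len(p), function(l)
    t(fit$coef[(2 * l - 1):(2 * l), , drop = FALSE]))
  comp <- matrix(0, 2 * p, 2 * p)
  for (l in seq_len(p)) comp[1:2, (2 * l - 1):(2 * l)] <- a_list[[l]]
  if (p > 1) comp[3:(2 * p), 1:(2 * p - 2)] <- diag(2 * p - 2)
  if (max(Mod(eigen(comp, only.values = TRUE)$values)) >= 1)
    stop("unstable VAR fit: companion roots on or inside the unit circle boundary")

  sig <- fit$sigma
  gc <- matrix(0, length(freqs), 2)
  for (j in seq_along(freqs)) {
    af <- diag(2) + 0i
    for (l in seq_len(p))
      af <- af - a_list[[l]] * exp(-2i * pi * freqs[j] * l / fs)
    h <- solve(af)
    s <- h %*% sig %*% Conj(t(h))
    s11 <- Re(s[1, 1]); s22 <- Re(s[2, 2])
    part_y <- sig[2, 2] - sig[1, 2]^2 / sig[1, 1]
    part_x <- sig[1, 1] - sig[1, 2]^2 / sig[2, 2]
    den_x <- s11 - part_y * Mod(h[1, 2])^2
    den_y <- s22 - part_x * Mod(h[2, 1])^2
    gc[j, 2] <- log(s11 / max(den_x, .Machine$double.eps))  # y -> x
    gc[j, 1] <- log(s22 / max(den_y, .Machine$double.eps))  # x -> y
  }
  gc <- pmax(gc, 0)
  dimnames(gc) <- list(format(freqs),
                       c(paste0(r$labels[1], "->", r$labels[2]),
                         paste0(r$labels[2], "->", r$labels[1])))
  structure(list(freqs = freqs, granger = gc, order = p,
                 sigma = sig, aic = aics),
            class = "spectral_granger")
}

#' @export
print.spectral_granger <- function(x, ...) {
  cat(sprintf("Spectral Granger causality (VAR order %d, %d frequencies %g-%g Hz)\n",
              x$order, length(x$freqs), min(x$freqs), max(x$freqs)))
  cat("Across-frequency means:\n")
  print(colMeans(x$granger))
  invisible(x)
}

#' Relative-influence normalisation of Granger spectra
#'
#' Divides each direction's Granger spectrum by its own across-frequency
#' mean, removing between-participant and between-region differences in
#' signal-to-noise scale; the output profile has across-frequency mean
#' exactly 1 in each direction.
#'
#' @param granger A `spectral_granger` object, a freq x direction matrix,
#'   or a single spectrum vector.
#' @return Same shape as the input (the `granger` component for
#'   `spectral_granger` input), normalised per direction.
#' @export
relative_influence <- function(granger) {
  if (inherits(granger, "spectral_granger")) granger <- granger$granger
  if (is.null(dim(granger))) granger <- matrix(granger, ncol = 1)
  mns <- colMeans(granger)
  if (any(mns <= 0)) stop("across-frequency mean must be positive")
  sweep(granger, 2, mns, `/`)
}

#' Cluster-corrected directionality contrast across subjects
#'
#' Tests, at every frequency, whether one direction's relative-influence
#' profile exceeds the other's across subjects (a within-subject paired
#' contrast), correcting over frequencies by suprathreshold-cluster mass
#' with a max-cluster sign-flip permutation null. A single frequency
#' degenerates to a paired t-test.
#'
#' @param profile_a,profile_b Subjects x frequency matrices of
#'   relative-influence profiles for the two directions (a minus b is
#'   tested).
#' @param freqs Frequency grid (defaults to column indices).
#' @param alpha Two-sided cluster-forming and cluster-level threshold.
#' @param n_permutations Sign-flip replicates (exhaustive if cheaper).
#' @param seed Integer seed.
#' @return A list of class `"directionality_contrast"`: `freqs`, `t`
#'   (per-frequency paired t), `clusters` (data frame: `from_hz`, `to_hz`,
#'   `sign`, `mass`, `p`), `sig_mask` (per-frequency logical), `alpha`.
#' @export
directionality_contrast <- function(profile_a, profile_b, freqs = NULL,
                                    alpha = 0.05, n_permutations = 1000L,
                                    seed = 1L) {
  a <- as.matrix(profile_a); b <- as.matrix(profile_b)
  if (!all(dim(a) == dim(b))) stop("profiles must have identical dimensions")
  n <- nrow(a)
  if (n < 3) stop("at least 3 subjects are required")
  if (is.null(freqs)) freqs <- seq_len(ncol(a))
  d <- a - b
  thr <- stats::qt(1 - alpha / 2, n - 1)

  tvec <- function(dd) {
    m <- colMeans(dd)
    s <- apply(dd, 2, stats::sd)
    s[s == 0] <- .Machine$double.eps
    m / (s / sqrt(n))
  }
  find_clusters <- function(tv) {
    supra <- ifelse(tv > thr, 1L, ifelse(tv < -thr, -1L, 0L))
    out <- list(); i <- 1L
    while (i <= length(supra)) {
      if (supra[i] != 0L) {
        j <- i
        while (j < length(supra) && supra[j + 1L] == supra[i]) j <- j + 1L
        out[[length(out) + 1L]] <- list(from = i, to = j, sign = supra[i],
                                        mass = sum(abs(tv[i:j])))
        i <- j + 1L
      } else i <- i + 1L
    }
    out
  }

  t_obs <- tvec(d)
  cl <- find_clusters(t_obs)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      flips <- sample(c(-1, 1), n, replace = TRUE)
      tv <- tvec(d * flips)
      cls <- find_clusters(tv)
      if (length(cls)) max(vapply(cls, `[[`, numeric(1), "mass")) else 0
    }, numeric(1))
  })

  sig_mask <- logical(length(freqs))
  clusters <- data.frame(from_hz = numeric(0), to_hz = numeric(0),
                         sign = integer(0), mass = numeric(0), p = numeric(0))
  for (c0 in cl) {
    p <- (1 + sum(null_max >= c0$mass)) / (n_permutations + 1)
    clusters <- rbind(clusters, data.frame(
      from_hz = freqs[c0$from], to_hz = freqs[c0$to],
      sign = c0$sign, mass = c0$mass, p = p))
    if (p <= alpha) sig_mask[c0$from:c0$to] <- TRUE
  }
  structure(list(freqs = freqs, t = t_obs, clusters = clusters,
                 sig_mask = sig_mask, alpha = alpha),
            class = "directionality_contrast")
}

#' @export
print.directionality_contrast <- function(x, ...) {
  cat(sprintf("Directionality contrast over %d frequencies (alpha = %g)\n",
              length(x$freqs), x$alpha))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  else cat("no suprathreshold clusters\n")
  invisible(x)
}
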