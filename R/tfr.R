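#' Morlet wavelet time-frequency decomposition
#'
#' Trial-averaged induced power by complex Morlet wavelet convolution with a
#' fixed number of cycles per frequency (default 7), on the 4-80 Hz grid in
#' 2 Hz steps. Edge samples without full wavelet support (within three
#' Gaussian SDs of either epoch edge at that frequency) are flagged invalid
#' rather than zero-padded into downstream statistics.
#'
#' @param trials Trials x samples numeric matrix (a single trial may be
#'   given as a vector).
#' @param fs Sampling rate, Hz (250 in this pipeline).
#' @param freqs Frequency grid, Hz; must stay below Nyquist.
#' @param cycles Wavelet cycles (time-frequency trade-off).
#' @param times_ms Optional time stamps; default `0, 1/fs, ...` in ms.
#' @return A list of class `"tf_map"`: `times` (ms), `freqs`, `power`
#'   (time x frequency, trial-averaged), `valid` (same shape, full-support
#'   flag), `rescaled = FALSE`, `fs`.
#' @export
morlet_tf <- function(trials, fs = 250, freqs = seq(4, 80, by = 2),
                      cycles = 7, times_ms = NULL) {
  if (is.null(dim(trials))) trials <- matrix(trials, nrow = 1)
  if (any(freqs >= fs / 2)) stop("requested frequencies at or above Nyquist")
  n <- ncol(trials); n_tr <- nrow(trials)
  if (is.null(times_ms)) times_ms <- (seq_len(n) - 1) / fs * 1000
  nfft <- stats::nextn(2L * n, 2)
  ft <- t(apply(trials, 1, function(x) stats::fft(c(x, numeric(nfft - n)))))
  if (n_tr == 1L) ft <- matrix(ft, nrow = 1)

  power <- matrix(0, n, length(freqs))
  valid <- matrix(TRUE, n, length(freqs))
  t_half <- (seq_len(nfft) - 1) / fs
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sd_t <- cycles / (2 * pi * f)
    # wavelet centred at lag 0, wrapped onto the padded circular grid
    tt <- ifelse(t_half > nfft / fs / 2, t_half - nfft / fs, t_half)
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sd_t^2))
    w <- w / sqrt(sum(Mod(w)^2))
    wf <- stats::fft(w)
    pj <- numeric(n)
    for (i in seq_len(n_tr)) {
      conv <- stats::fft(ft[i, ] * Conj(wf), inverse = TRUE) / nfft
      pj <- pj + Mod(conv[seq_len(n)])^2
    }
    power[, j] <- pj / n_tr
    half_support <- 3 * sd_t
    valid[, j] <- (seq_len(n) - 1) / fs >= half_support &
      (n - seq_len(n)) / fs >= half_support
  }
  structure(list(times = times_ms, freqs = freqs, power = power,
                 valid = valid, rescaled = FALSE, fs = fs),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("Time-frequency map: %d times (%.0f-%.0f ms) x %d freqs (%g-%g Hz)%s\n",
              length(x$times), min(x$times), max(x$times), length(x$freqs),
              min(x$freqs), max(x$freqs),
              if (x$rescaled) ", baseline log-rescaled" else ""))
  invisible(x)
}

#' Log-rescale a time-frequency map to a pre-stimulus baseline
#'
#' Power at each frequency is expressed in decibels relative to the mean
#' baseline power of that frequency band:
#' `10 * log10(power(t, f) / mean baseline power(f))`, the baseline window
#' lying before written-word onset in the experimental epochs.
#'
#' @param tf A non-rescaled `tf_map`.
#' @param baseline_window Length-2 numeric, ms, inside the epoch.
#' @return The rescaled `tf_map` (flagged `rescaled = TRUE`).
#' @export
baseline_log_rescale <- function(tf, baseline_window) {
  stopifnot(inherits(tf, "tf_map"))
  if (tf$rescaled) stop("map is already baseline-rescaled")
  sel <- tf$times >= baseline_window[1] & tf$times <= baseline_window[2]
  if (!any(sel)) stop("baseline window lies outside the epoch")
  base <- vapply(seq_along(tf$freqs), function(j) {
    ok <- sel & tf$valid[, j]
    if (!any(ok)) ok <- sel
    mean(tf$power[ok, j])
  }, numeric(1))
  if (any(base <= 0)) stop("zero baseline power at some frequency")
  tf$power <- 10 * log10(sweep(tf$power, 2, base, `/`))
  tf$rescaled <- TRUE
  tf
}

#' Subtract the condition-mean evoked waveform from every trial
#'
#' Removes the phase-locked (evoked) response so that later spectral
#' analysis reflects induced activity: each trial has its condition's mean
#' waveform subtracted, leaving residual trials with zero condition means.
#'
#' @param trials Trials x samples matrix, or a `source_trials` object (both
#'   regions are residualised using its condition labels).
#' @param condition Per-trial condition labels (ignored for
#'   `source_trials`).
#' @return Residual trials of the same shape/class as the input.
#' @export
subtract_evoked <- function(trials, condition = NULL) {
  if (inherits(trials, "source_trials")) {
    cond <- trials$condition
    trials$frontal <- subtract_evoked(trials$frontal, cond)
    trials$temporal <- subtract_evoked(trials$temporal, cond)
    return(trials)
  }
  if (is.null(condition)) condition <- rep("all", nrow(trials))
  if (length(condition) != nrow(trials))
    stop("`condition` must have one label per trial")
  counts <- table(condition)
  if (any(counts < 2))
    stop("every condition needs at least 2 trials to estimate its evoked waveform")
  for (g in names(counts)) {
    rows <- condition == g
    m <- colMeans(trials[rows, , drop = FALSE])
    trials[rows, ] <- sweep(trials[rows, , drop = FALSE], 2, m)
  }
  trials
}

#' Latency at which the beta-band congruency contrast reaches 80% of peak
#'
#' The congruency contrast is the band-mean (default 12-24 Hz) difference
#' in rescaled power, mismatch minus match (matching cues suppress power in
#' this band, so the contrast is positive at effect). The peak is located
#' inside the search window and the latency is the earliest time at which
#' the contrast reaches `fraction` (default 0.8) of that peak. A
#' non-positive peak yields an explicitly undefined (flagged) latency.
#'
#' @param tf_match,tf_mismatch `tf_map` objects on identical grids with the
#'   same rescaling state.
#' @param band Frequency band, Hz.
#' @param fraction Fraction of peak defining the latency.
#' @param search_window Time window searched, ms.
#' @param absolute If `TRUE`, use the absolute contrast instead of the
#'   signed mismatch-minus-match convention.
#' @return A list of class `"band_contrast"`: `times`, `values` (contrast
#'   time course over the window), `peak_value`, `peak_time_ms`, `t80_ms`,
#'   `fraction`, `band_hz`, `defined` (FALSE when the peak is not
#'   positive, in which case `t80_ms` is `NA`).
#' @export
band_contrast_latency <- function(tf_match, tf_mismatch, band = c(12, 24),
                                  fraction = 0.8,
                                  search_window = c(0, 1000),
                                  absolute = FALSE) {
  stopifnot(inherits(tf_match, "tf_map"), inherits(tf_mismatch, "tf_map"))
  if (!isTRUE(all.equal(tf_match$times, tf_mismatch$times)) ||
      !isTRUE(all.equal(tf_match$freqs, tf_mismatch$freqs)))
    stop("maps must share time and frequency grids")
  if (tf_match$rescaled != tf_mismatch$rescaled)
    stop("maps must share the same rescaling state")

  fsel <- tf_match$freqs >= band[1] & tf_match$freqs <= band[2]
  if (!any(fsel)) stop("band contains no frequency bins")
  contrast <- rowMeans(tf_mismatch$power[, fsel, drop = FALSE] -
                         tf_match$power[, fsel, drop = FALSE])
  ok_t <- tf_match$times >= search_window[1] & tf_match$times <= search_window[2]
  full <- rowSums(!(tf_match$valid[, fsel, drop = FALSE] &
                      tf_mismatch$valid[, fsel, drop = FALSE])) == 0
  ok_t <- ok_t & full
  if (!any(ok_t)) stop("no valid samples inside the search window")
  times <- tf_match$times[ok_t]
  v <- contrast[ok_t]
  if (absolute) v <- abs(v)

  peak <- max(v)
  if (peak <= 0) {
    return(structure(list(times = times, values = v, peak_value = peak,
                          peak_time_ms = NA_real_, t80_ms = NA_real_,
                          fraction = fraction, band_hz = band,
                          defined = FALSE),
                     class = "band_contrast"))
  }
  peak_t <- times[which.max(v)]
  t80 <- times[which(v >= fraction * peak)[1]]
  structure(list(times = times, values = v, peak_value = peak,
                 peak_time_ms = peak_t, t80_ms = t80,
                 fraction = fraction, band_hz = band, defined = TRUE),
            class = "band_contrast")
}

#' @export
print.band_contrast <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("Band contrast %g-%g Hz: peak %.4g at %g ms; t%d = %g ms\n",
                x$band_hz[1], x$band_hz[2], x$peak_value, x$peak_time_ms,
                round(100 * x$fraction), x$t80_ms))
  } else {
    cat(sprintf("Band contrast %g-%g Hz: no positive peak; latency undefined\n",
                x$band_hz[1], x$band_hz[2]))
  }
  invisible(x)
}
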