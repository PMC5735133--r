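#' True generating parameters for a simulated listener
#'
#' @param sigma_prior Standard deviation of the prior expectation (> 0,
#'   arbitrary units; smaller = more precise priors).
#' @param threshold Perceptual threshold (>= 0, same units as posterior
#'   precision).
#' @param rating_noise_sd Trial-level Gaussian rating noise SD on the 1-4
#'   scale (>= 0).
#' @param identification_ability Logistic offset of 4AFC identification
#'   skill (larger = better word report).
#' @return A list of class `"perceptual_parameters"`.
#' @export
perceptual_parameters <- function(sigma_prior, threshold = 0.05,
                                  rating_noise_sd = 0.3,
                                  identification_ability = 1) {
  if (sigma_prior <= 0) stop("`sigma_prior` must be positive")
  if (threshold < 0) stop("`threshold` must be non-negative")
  if (rating_noise_sd < 0) stop("`rating_noise_sd` must be non-negative")
  structure(list(sigma_prior = sigma_prior, threshold = threshold,
                 rating_noise_sd = rating_noise_sd,
                 identification_ability = identification_ability),
            class = "perceptual_parameters")
}

## 4AFC accuracy model: logit = ability + b_channels*log2(channels/4)
## - b_neighbours*n_neighbours, with the 4AFC chance floor.
exp2_accuracy <- function(ability, channels, n_neighbours,
                          b_channels = 1, b_neighbours = 0.5) {
  0.25 + 0.75 * stats::plogis(ability + b_channels * log2(channels / 4) -
                                b_neighbours * n_neighbours)
}

## Expected per-channel identification accuracy under the Exp2 case mix
## (10, 5, 5, 10 trials speaking words with 2, 1, 1, 0 array neighbours).
true_channel_accuracy <- function(ability, channels = c(4L, 8L, 16L)) {
  wts <- c(10, 5, 5, 10) / 30
  nn <- c(2L, 1L, 1L, 0L)
  vapply(channels, function(ch)
    sum(wts * exp2_accuracy(ability, ch, nn)), numeric(1))
}

#' Simulate one listener's behavioural data
#'
#' Generates per-trial clarity ratings (Experiment 1) through the forward
#' perceptual model - posterior precision from the listener's true sensory
#' precision, threshold-anchored mapping to the 1-4 scale, plus Gaussian
#' rating noise, rounded half-up and clipped - and per-trial 4AFC
#' identification outcomes (Experiment 2) from a logistic accuracy model
#' with a 0.25 chance floor.
#'
#' @param params A [perceptual_parameters()] object.
#' @param exp1 An [exp1_schedule()] (or any data frame with `congruency` and
#'   `channels` columns).
#' @param exp2 An [exp2_schedule()].
#' @param seed Integer seed; the dataset is deterministic given it.
#' @return A list of class `"subject_dataset"`: `exp1` (trial table with
#'   `rating`), `exp2` (trial table with `correct`), `precision` (the
#'   sensory-precision table derived from the true identification
#'   probabilities: columns `channels`, `accuracy`, `s`),
#'   `precision_measured` (same, from observed Exp2 accuracy), and
#'   `params` (the hidden truth).
#' @export
simulate_subject <- function(params, exp1, exp2, seed) {
  stopifnot(inherits(params, "perceptual_parameters"))
  exp1 <- as.data.frame(exp1); exp2 <- as.data.frame(exp2)
  channels <- c(4L, 8L, 16L)

  acc_true <- true_channel_accuracy(params$identification_ability, channels)
  s_true <- sensory_precision(acc_true)
  precision <- data.frame(channels = channels, accuracy = acc_true, s = s_true)

  mu <- predict_conditions(params$sigma_prior, params$threshold, precision)
  if (is.null(mu))
    stop("degenerate listener: every posterior precision is below threshold")
  grid <- condition_grid()
  idx <- match(paste(exp1$congruency, exp1$channels),
               paste(grid$congruency, grid$channels))
  if (anyNA(idx)) stop("`exp1` contains conditions outside the 2 x 3 design")

  with_seed(seed, {
    r <- mu[idx] + stats::rnorm(nrow(exp1), 0, params$rating_noise_sd)
    exp1$rating <- pmin(4, pmax(1, round_half_up(r)))

    p_corr <- exp2_accuracy(params$identification_ability, exp2$channels,
                            exp2$n_neighbours_in_array)
    exp2$correct <- stats::rbinom(nrow(exp2), 1L, p_corr)
  })

  acc_hat <- vapply(channels, function(ch)
    mean(exp2$correct[exp2$channels == ch]), numeric(1))
  structure(list(
    exp1 = exp1, exp2 = exp2,
    precision = precision,
    precision_measured = data.frame(channels = channels, accuracy = acc_hat,
                                    s = sensory_precision(acc_hat)),
    params = params
  ), class = "subject_dataset")
}

#' Specify a two-group synthetic cohort
#'
#' Defaults emulate the study conditions: 11 listeners per group; patients
#' draw stochastically smaller prior SDs than controls (more precise
#' priors), slightly lower identification ability, identical thresholds and
#' rating noise (0.3 on the rating scale, the study-scale noise level used
#' for the recovery properties).
#'
#' @param n_per_group Listeners per group.
#' @param control,patient Named lists of group-level sampling parameters:
#'   `sigma_meanlog`/`sigma_sdlog` (lognormal prior SD),
#'   `threshold_range` (uniform), `ability_mean`/`ability_sd` (normal),
#'   `rating_noise_sd`.
#' @param seed Integer seed.
#' @return List of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_group = 11L,
                        control = list(sigma_meanlog = log(1.0), sigma_sdlog = 0.35,
                                       threshold_range = c(0.02, 0.12),
                                       ability_mean = 1.0, ability_sd = 0.4,
                                       rating_noise_sd = 0.3),
                        patient = list(sigma_meanlog = log(0.45), sigma_sdlog = 0.35,
                                       threshold_range = c(0.02, 0.12),
                                       ability_mean = 0.6, ability_sd = 0.4,
                                       rating_noise_sd = 0.3),
                        seed = 1L) {
  structure(list(n_per_group = as.integer(n_per_group),
                 control = control, patient = patient, seed = seed),
            class = "cohort_spec")
}

#' Simulate a two-group cohort with known ground truth
#'
#' Draws each listener's hidden generating parameters from their group's
#' distributions, builds per-listener Experiment 1/2 schedules (fresh seeds
#' per listener from the cohort seed), and simulates behaviour with
#' [simulate_subject()].
#'
#' @param spec A [cohort_spec()].
#' @param word_pool Word ids for the Experiment 1 schedules (default 432
#'   synthetic words: 216 spoken twice, 216 once).
#' @return A list of class `"cohort"`: one element per listener with
#'   `group`, `id`, `dataset` (a `subject_dataset`) and `params` (the
#'   truth).
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            word_pool = sprintf("w%03d", 1:432)) {
  stopifnot(inherits(spec, "cohort_spec"))
  rs <- make_response_sets()
  draw_group <- function(g, label, seed_off) {
    n <- spec$n_per_group
    pars <- with_seed(child_seed(spec$seed, seed_off), {
      sig <- stats::rlnorm(n, g$sigma_meanlog, g$sigma_sdlog)
      th <- stats::runif(n, g$threshold_range[1], g$threshold_range[2])
      ab <- stats::rnorm(n, g$ability_mean, g$ability_sd)
      Map(function(s, t, a)
        perceptual_parameters(s, t, g$rating_noise_sd, a), sig, th, ab)
    })
    lapply(seq_len(n), function(i) {
      sseed <- child_seed(spec$seed, seed_off * 1000L + i)
      sched1 <- exp1_schedule(word_pool,
                              order_label = if (i %% 2 == 1) "A" else "B",
                              seed = sseed)
      sched2 <- exp2_schedule(rs, seed = sseed)
      list(group = label, id = sprintf("%s%02d", label, i),
           params = pars[[i]],
           dataset = simulate_subject(pars[[i]], sched1, sched2,
                                      seed = child_seed(sseed, 7L)))
    })
  }
  structure(c(draw_group(spec$control, "control", 11L),
              draw_group(spec$patient, "patient", 29L)),
            class = "cohort")
}

#' Coupling specification for simulated oscillatory source pairs
#'
#' @param direction One of `"frontal->temporal"`, `"temporal->frontal"`,
#'   `"none"`, `"bidirectional"`.
#' @param band_hz Frequency band of the directed influence, Hz.
#' @param lag_samples Transmission lag in samples (>= 1; imaginary coherence
#'   needs a non-zero lag).
#' @param strength Fraction of the receiver's variance contributed by the
#'   driver, in \[0, 1).
#' @return List of class `"coupling_spec"`.
#' @export
coupling_spec <- function(direction = c("frontal->temporal",
                                        "temporal->frontal",
                                        "none", "bidirectional"),
                          band_hz = c(13, 23), lag_samples = 3L,
                          strength = 0.3) {
  direction <- match.arg(direction)
  if (lag_samples < 1) stop("`lag_samples` must be >= 1 (zero-lag coupling has no imaginary part)")
  if (strength < 0 || strength >= 1) stop("`strength` must lie in [0, 1)")
  structure(list(direction = direction, band_hz = band_hz,
                 lag_samples = as.integer(lag_samples), strength = strength),
            class = "coupling_spec")
}

## Band-limited unit-variance driver process, n x len: a causal AR(2)
## resonator centred in the band (a strictly causal generator, so that a
## lagged copy carries no reverse-direction predictive information).
band_noise <- function(n, len, band_hz, fs) {
  f0 <- mean(band_hz)
  if (f0 >= fs / 2) stop("band centre at or above Nyquist")
  # pole radius set so the resonance half-width roughly matches the band
  r <- min(0.97, max(0.85, 1 - pi * diff(range(band_hz)) / 2 / fs))
  a1 <- 2 * r * cos(2 * pi * f0 / fs); a2 <- -r^2
  burn <- 200L
  out <- matrix(0, n, len)
  for (i in seq_len(n)) {
    x <- stats::filter(stats::rnorm(len + burn), c(a1, a2),
                       method = "recursive")
    x <- as.numeric(x)[(burn + 1):(burn + len)]
    out[i, ] <- x / stats::sd(x)
  }
  out
}

#' Simulate a coupled pair of oscillatory sources
#'
#' Two-region (frontal, temporal) per-trial time series at 250 Hz over the
#' 0-912 ms post-speech window (228 samples). The driver region carries a
#' unit-variance band-limited signal (a causal AR(2) resonator centred in
#' the band); the receiver carries independent unit-variance white noise
#' plus a lagged copy of the driver signal, scaled so that `strength` is
#' the fraction of receiver variance it contributes. Because the driver
#' observes its own signal noiselessly and the generator is strictly
#' causal, directed influence flows only along the requested direction.
#' With `direction = "none"` both regions are independent white noise.
#'
#' @param spec A [coupling_spec()].
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param condition Optional per-trial condition labels (recycled).
#' @return List of class `"source_trials"`: `frontal` and `temporal`
#'   (`n_trials` x 228 matrices), `fs` (250), `times_ms`, `condition`.
#' @export
simulate_coupled_sources <- function(spec, n_trials = 100L, seed = 1L,
                                     condition = "all") {
  stopifnot(inherits(spec, "coupling_spec"))
  fs <- 250; len <- 228L
  lag <- spec$lag_samples
  a <- sqrt(spec$strength / (1 - spec$strength))
  with_seed(seed, {
    noise_f <- matrix(stats::rnorm(n_trials * len), n_trials)
    noise_t <- matrix(stats::rnorm(n_trials * len), n_trials)
    shift <- function(b, k) cbind(b[, seq_len(k), drop = FALSE] * 0,
                                  b[, seq_len(ncol(b) - k), drop = FALSE])
    frontal <- noise_f; temporal <- noise_t
    if (spec$direction %in% c("frontal->temporal", "bidirectional")) {
      b <- band_noise(n_trials, len, spec$band_hz, fs)
      frontal <- if (spec$direction == "bidirectional") frontal + b else b
      temporal <- temporal + a * shift(b, lag)
    }
    if (spec$direction %in% c("temporal->frontal", "bidirectional")) {
      b <- band_noise(n_trials, len, spec$band_hz, fs)
      temporal <- if (spec$direction == "bidirectional") temporal + b else b
      frontal <- frontal + a * shift(b, lag)
    }
    structure(list(frontal = frontal, temporal = temporal, fs = fs,
                   times_ms = (seq_len(len) - 1) / fs * 1000,
                   condition = rep_len(condition, n_trials)),
              class = "source_trials")
  })
}

#' Simulate a time-frequency contrast pair with an implanted latency
#'
#' Builds a matched pair of baseline-rescaled time-frequency maps (match,
#' mismatch) whose 12-24 Hz band-mean contrast (mismatch minus match) rises
#' piecewise-linearly and first reaches 80% of its peak at `latency_ms`, up
#' to one 4 ms sample. Ground truth for [band_contrast_latency()].
#'
#' @param latency_ms Implanted 80%-of-peak latency, within 0-1000 ms.
#' @param peak_freq_hz Centre of the Gaussian frequency profile (default
#'   18 Hz, mid-beta).
#' @param amplitude Peak band-mean contrast (0 gives flat maps and an
#'   undefined latency downstream).
#' @param seed Integer seed for the low-level background noise.
#' @return List with elements `match` and `mismatch`, both `tf_map` objects
#'   (rescaled), on a 0-1000 ms / 4 ms grid, 4-80 Hz in 2 Hz steps.
#' @export
simulate_tf_contrast <- function(latency_ms, peak_freq_hz = 18,
                                 amplitude = 1, seed = 1L) {
  times <- seq(0, 1000, by = 4)
  freqs <- seq(4, 80, by = 2)
  if (latency_ms < 0 || latency_ms > max(times))
    stop("`latency_ms` must lie within the 0-1000 ms analysis window")
  rise <- min(100, latency_ms / 0.8)
  t0 <- latency_ms - 0.8 * rise
  tp <- t0 + rise
  r <- pmin(1, pmax(0, if (rise > 0) (times - t0) / rise else as.numeric(times >= t0)))
  fprof <- exp(-0.5 * ((freqs - peak_freq_hz) / 4)^2)
  band <- freqs >= 12 & freqs <= 24
  scale <- if (mean(fprof[band]) > 0) amplitude / mean(fprof[band]) else 0
  base <- outer(r, fprof) * scale
  mk <- function(power) {
    structure(list(times = times, freqs = freqs, power = power,
                   valid = matrix(TRUE, length(times), length(freqs)),
                   rescaled = TRUE, fs = 250),
              class = "tf_map")
  }
  # seeded background texture, kept out of the analysis band so it cannot
  # perturb the implanted crossing
  noise <- with_seed(seed, matrix(stats::rnorm(length(base), 0, amplitude * 1e-4),
                                  nrow(base)))
  noise[, band] <- 0
  list(match = mk(base * 0), mismatch = mk(base + noise))
}

#' Noise-vocode a waveform
#'
#' Envelope vocoding: the input is split into `n_channels` bands equally
#' spaced on a log-frequency axis between 70 and 5000 Hz; each band's
#' envelope (half-wave rectified, low-passed at 30 Hz) modulates
#' band-matched white noise, and the bands are summed. More channels retain
#' more spectral detail. Output is RMS-matched to the input.
#'
#' @param waveform Finite mono numeric vector.
#' @param n_channels Number of vocoder bands (>= 1).
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed for the carrier noise.
#' @param band_range Outer band edges, Hz.
#' @return Numeric vector of the same length and sampling rate.
#' @export
vocode <- function(waveform, n_channels, fs = 16000, seed = 1L,
                   band_range = c(70, 5000)) {
  if (n_channels < 1) stop("`n_channels` must be >= 1")
  if (!is.numeric(waveform) || any(!is.finite(waveform)))
    stop("`waveform` must be a finite numeric vector")
  len <- length(waveform)
  edges <- exp(seq(log(band_range[1]), log(band_range[2]),
                   length.out = n_channels + 1))
  freqs <- (seq_len(len) - 1) * fs / len
  freqs <- pmin(freqs, fs - freqs)
  bandpass <- function(x, lo, hi) {
    z <- stats::fft(x)
    z[!(freqs >= lo & freqs < hi)] <- 0
    Re(stats::fft(z, inverse = TRUE)) / len
  }
  lowpass <- function(x, hi) {
    z <- stats::fft(x)
    z[freqs > hi] <- 0
    Re(stats::fft(z, inverse = TRUE)) / len
  }
  out <- with_seed(seed, {
    acc <- numeric(len)
    for (k in seq_len(n_channels)) {
      band <- bandpass(waveform, edges[k], edges[k + 1])
      env <- pmax(0, lowpass(pmax(band, 0), 30))
      carrier <- bandpass(stats::rnorm(len), edges[k], edges[k + 1])
      acc <- acc + env * carrier
    }
    acc
  })
  rms_in <- sqrt(mean(waveform^2)); rms_out <- sqrt(mean(out^2))
  if (rms_out > 0) out <- out * rms_in / rms_out
  out
}
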