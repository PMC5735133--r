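# priorclarity

Listeners hearing acoustically degraded (noise-vocoded) speech rate it as
clearer when a written cue told them what word was coming. `priorclarity`
implements a hierarchical Bayesian ideal-observer account of that effect and
the analysis machinery built around it: the factorial trial designs, a
ground-truth synthetic cohort generator for parameter-recovery studies, the
between-group statistics, and the oscillatory (MEG-style) neural statistics
used to track when and how prior knowledge reshapes perception. It is aimed
at researchers in psychophysics and cognitive neuroscience who want a
tested, reproducible reference implementation of this model family — for
example to study populations (such as non-fluent aphasia) suspected of
applying abnormally precise prior expectations.

## The model

Each listener's sensory precision at `c` vocoder channels is their
word-identification accuracy above chance,

    s_c = max(0, (acc_c − 0.25) / 0.75),

measured in a separate 4-alternative forced-choice task. The precision of
the posterior percept multiplies sensory precision by a weighted function of
the prior's precision (`w = 0.5` for matching cues — half the cues in the
experiment matched — and `w = 0` for mismatching or neutral cues):

    P = s_c · (1 + w / σ²),

where `σ` is the standard deviation of the listener's prior expectation.
Posterior precision below a perceptual threshold `θ` is rated 1 (completely
unclear); above it, clarity maps linearly onto the 1–4 rating scale,
anchored so the listener's maximum condition precision rates 4:

    rating = 1 + 3 · (P − θ) / (P_ref − θ),   clipped to [1, 4].

`fit_clarity()` estimates `(σ, θ)` per listener by seeded multi-start
bounded least squares over the six condition means of the 2 (match /
mismatch) × 3 (4/8/16 channels) design. A three-parameter variant
additionally frees the match weighting for 16-channel speech (emulating
psychometric saturation at high sensory detail); `compare_variants()`
adjudicates by small-sample AICc,

    AICc = n·ln(RSS/n) + 2k + 2k(k+1)/(n − k − 1).

The neural statistics mirror the behavioural model's predictions in time:
Morlet time–frequency power (4–80 Hz, 7 cycles) with baseline
log-rescaling, the 12–24 Hz match-vs-mismatch contrast latency (first time
reaching 80 % of peak), multitaper (±4 Hz) imaginary coherence and
Geweke-decomposed spectral Granger causality between frontal and temporal
sources, each with trial-shuffle permutation nulls, relative-influence
normalisation, and a cluster-corrected directionality contrast.

## Worked example

Simulate one listener with known parameters, then recover them:

```r
library(priorclarity)

sched1 <- exp1_schedule(sprintf("w%03d", 1:432), seed = 11)   # 648 rating trials
sched2 <- exp2_schedule(make_response_sets(), seed = 11)      # 90 4AFC trials
truth  <- perceptual_parameters(sigma_prior = 0.6, threshold = 0.08,
                                rating_noise_sd = 0.3,
                                identification_ability = 1)
dat <- simulate_subject(truth, sched1, sched2, seed = 12)

fit <- fit_clarity(dat, seed = 1)
summary(fit)
```

```
Bayesian clarity model (simple variant)
Coefficients:
sigma_prior   threshold 
     0.5648      0.0000 
RSS 0.001289 on 6 condition means; AICc -42.672; variance explained 100.0%
Note: solution lies on a parameter bound

Condition means:
 congruency channels observed fitted residual
      match        4   3.0093 3.0165  -0.0073
      match        8   3.6389 3.6431  -0.0042
      match       16   3.9815 4.0000  -0.0185
   mismatch        4   1.8056 1.7854   0.0202
   mismatch        8   2.0370 2.0294   0.0076
   mismatch       16   2.1481 2.1684  -0.0203
```

The generating `σ = 0.6` comes back as 0.565 from 108 noisy trials per
condition (ratings are discretised to four buttons, so the threshold — here
truly 0.08, a small number on the posterior-precision scale — is the harder
parameter; with rating noise it often sits on a bound). The rating gap
between match and mismatch columns is the congruency effect: the more
precise the prior (smaller `σ`), the larger the gap. Comparing variants:

```r
compare_variants(fit, fit_clarity(dat, variant = "complex", seed = 1))
```

```
Model comparison (AICc, corrected for small samples)
  simple : -42.672
  complex: -32.956
  preferred: simple (delta AICc = 9.716)
```

`run_pipeline(run_config(seed = 1))` chains design → cohort simulation →
fitting → group statistics → neural statistics and writes per-stage CSV/JSON
artefacts with a digest manifest; `pipeline_report()` prints the summary
tables.

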