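---
title: "Models and methods in priorclarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in priorclarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorclarity)
```

This vignette is the package's own account of its science: the perceptual
model and its assumptions, the experimental designs it is fitted to, what
the synthetic-data generators do and do not emulate, the neural statistics,
and the numerical and design choices made where the published description
left the design open.

## The perceptual inference model

The model treats clarity rating of degraded speech as perceptual inference:
the percept combines the sensory input with a prior expectation induced by a
written cue, and subjective clarity tracks the precision of the resulting
posterior.

**Sensory precision.** Each listener's sensory precision at `c` vocoder
channels is defined from their measured 4-alternative forced-choice
word-identification accuracy, as proportion correct above the 0.25 chance
floor rescaled to [0, 1] (`sensory_precision()`). This deliberately ties
the model's sensory front end to an independent measurement rather than a
free parameter, so the two fitted parameters describe only the listener's
use of prior knowledge.

**Posterior precision.** The posterior precision multiplies the sensory
precision by a weighted function of the prior's precision. The exact
analytic form of that weighted function is not pinned down by the verbal
description, so the package adopts

$$P = s \cdot \left(1 + \frac{w}{\sigma^2}\right),$$

which (a) is multiplicative as described, (b) reduces exactly to $P = s$
when $w = 0$ — the stated behaviour for mismatching and neutral cues — and
(c) is monotone in the prior precision $1/\sigma^2$. The congruency
weighting is fixed at $w = 0.5$ for matching cues, reflecting an
experimental context in which half the cues matched, and $0$ otherwise
(in open-set listening the prior weight on any particular uncued word is
negligible). Freeing $w$ would be mathematically equivalent to freeing
$\sigma$, which is why "excessively precise priors" and "inflexible
priors" are interchangeable descriptions of a small fitted $\sigma$.

**Clarity mapping.** Posterior precision at or below a perceptual
threshold $\theta$ is rated 1 (completely unclear). Above it, clarity maps
linearly to the rest of the 1–4 scale with the listener's *maximum*
condition precision anchored at 4. The full-range anchor implements the
instruction that participants use the whole rating scale; it also means
ratings are relative within listener, so fitted parameters — not raw
ratings — are the quantities comparable across listeners.

**Assumptions worth stating.** The mapping is linear above threshold; the
weighting is condition-constant (no saturation with sensory detail — that
is exactly what the complex variant relaxes); ratings are treated at the
condition-mean level; and sensory precision is noiseless once measured.

## Fitting and model comparison

`fit_clarity()` minimises the squared residuals between observed and
predicted condition means over the six cells of the 2 × 3 design. Fitting
condition means (n = 6) rather than single trials keeps the AICc
small-sample correction meaningful (with k = 3 it requires n ≥ 5) and
matches how such fits are usually displayed and compared.

The "global" minimisation is a seeded multi-start strategy: 32
Latin-hypercube starting points (plus two deterministic anchors) in the box
$\log\sigma \in [\log 10^{-3}, \log 10^{3}]$, $\theta \in [0, 0.999\,s_{\max}]$
(and $w_{16} \in [0,1]$ for the complex variant), each polished by L-BFGS-B.
$\sigma$ is searched on a log scale because the objective is flat in
$\sigma$ once $w/\sigma^2$ is negligible. Parameter sets under which every
condition falls below threshold (an "all-unclear" listener) receive a large
penalty rather than an error inside the optimiser. Determinism: the same
seed always reproduces the same fit; the test suite verifies the optimiser
never loses to a 100 × 100 grid search.

Degenerate data (zero variance across condition means) yield a boundary
solution with a warning flag rather than a failure. When match and mismatch
means coincide, the best fit drives the prior's contribution to nil
($\sigma$ at its upper bound) *provided* the channel profile is consistent
with the sensory-precision table; the package does not force this outcome
when an interior optimum genuinely fits better.

`compare_variants()` uses the RSS-based AICc,
$n\ln(\mathrm{RSS}/n) + 2k + 2k(k+1)/(n-k-1)$, with ties broken toward the
simple model (parsimony). Both fits must hash to the same observed data.

## Experimental designs

Three schedules are generated exactly, with seeded determinism:

* **Clarity rating (Experiment 1):** 108 trials per condition of the
  2 (congruency) × 3 (4/8/16 channels) design, across six blocks of 18 per
  cell, in one of two fixed seed-derived orders. Spoken words recur at most
  twice per listener, once per congruency level; mismatch trials draw their
  written cue from another mismatch trial's spoken word, so cues and speech
  never share a word. Cue→speech and speech→probe intervals jitter
  uniformly in 1050 ± 50 ms (the distribution of the jitter is not
  specified anywhere; uniform is the minimal assumption). The published
  token bookkeeping (216 words twice + 108 once) does not close against
  648 trials, so the generator treats the per-condition counts and reuse
  caps as primary, fills greedily, and reports the realised twice/once
  tallies in the schedule summary; the default 432-word pool realises 216
  words spoken twice and 216 once.
* **4AFC identification (Experiment 2):** 90 trials; 30 four-word response
  sets (target, offset neighbour, onset neighbour, unrelated), each
  presented once per channel level with a different member spoken, giving
  per-channel case tallies 10/5/5/10 and 2/1/1/0 neighbours in the array.
  The channel/difficulty slot order is fixed; which set fills which slot is
  seeded, via a balanced Latin-square rotation.
* **Neutral replication:** one block, 18 trials per cell of the 3 × 3
  design, neutral trials carrying an explicit uninformative cue token.

Phonological structure is modelled only as word identity; mismatch means
"different word", with no feature-level overlap model.

## Synthetic cohorts and what they do (not) show

`simulate_cohort()` produces listeners with known parameters, the ground
truth for every recovery property. Group distributions were chosen once to
emulate the study conditions and are not tuned: 11 listeners per group;
prior SD lognormal with median 1.0 (controls) versus 0.45 (patients,
stochastically more precise), sdlog 0.35; thresholds uniform on
[0.02, 0.12]; trial-level rating noise SD 0.3 on the rating scale;
identification ability normal with mean 1.0 (controls) / 0.6 (patients),
SD 0.4, which puts controls near ceiling at 16 channels while keeping all
listeners above chance at 4. The 4AFC accuracy model is
$0.25 + 0.75\,\mathrm{logistic}(\mathrm{ability} + \log_2(c/4) - 0.5\,n_{\mathrm{neigh}})$
— the published analysis reports monotone effects of channels and
neighbour count but no functional form, so a logistic with the 4AFC chance
floor is used. Single-trial ratings are the predicted condition mean plus
Gaussian noise, rounded half-up and clipped to [1, 4]; the original model
was fitted to condition means, so this noise model is a stand-in for test
purposes, not a claim about the source data.

Recovery fits use the sensory-precision table derived from the listener's
*true* identification probabilities (the empirical Exp2 estimate is also
carried in the dataset). The recovery properties are meant to test the
fitting machinery; routing the 30-trial-per-channel Exp2 sampling noise
into them would conflate two error sources.

Passing these properties shows the estimator is consistent and
well-calibrated *under the model's own assumptions* with realistic trial
counts and noise. It does not show that real listeners obey the linear
mapping, that rating noise is Gaussian, or that sensory precision is
stable over a session.

## Neural statistics

**Time–frequency power.** Morlet wavelets with 7 cycles on 4–80 Hz in 2 Hz
steps (39 bins); power is trial-averaged, and samples without full wavelet
support (within three Gaussian SDs of an epoch edge at that frequency) are
masked rather than zero-padded into statistics. Baseline rescaling is
$10\log_{10}$ of the ratio to the mean pre-stimulus baseline power per
frequency ("log rescaled" admits several conventions; decibels are the
field's default).

**Congruency-contrast latency.** The contrast is the 12–24 Hz band-mean
difference of rescaled power, *mismatch minus match* (matching cues
suppress power in this band, making the contrast positive at effect; an
absolute-value fallback is available by flag). The latency is the earliest
time, within a 0–1000 ms search window at 4 ms resolution and with no
smoothing, at which the contrast reaches 80 % of its in-window peak. A
non-positive peak yields an explicitly undefined latency, never a silent
zero. `simulate_tf_contrast()` closes the loop: it builds map pairs whose
80 %-crossing sits at a requested latency (a piecewise-linear rise under a
Gaussian 18 Hz-centred frequency profile), and the suite verifies recovery
within one sample across 50 implants, plus complete separation of two
groups implanted with 275–400 ms versus 412–1000 ms latencies (the upper
end is capped at the search window, within which latencies are
recoverable by construction).

**Connectivity.** Spectra use Slepian multitapers with a ±4 Hz smoothing
half-bandwidth over the 0–912 ms window at 250 Hz (228 samples), giving
$K = \lfloor 2TW - 1\rfloor = 6$ tapers; the tapers are computed from the
standard symmetric tridiagonal eigenproblem. Imaginary coherence is
$|\mathrm{Im}(S_{xy}/\sqrt{S_{xx}S_{yy}})|$ of trial-and-taper-averaged
spectra, immune to zero-lag (volume-conducted) coupling — the suite
asserts both that property and detection of a quarter-cycle-lagged common
component. Spectral Granger causality fits a bivariate VAR by least
squares pooled across evoked-subtracted trials (order by AIC up to a cap;
unstable fits rejected) and applies the Geweke decomposition. A parametric
VAR estimator is used rather than a nonparametric spectral factorisation;
acceptance is therefore against simulation ground truth, not numeric
parity with any particular toolbox. Permutation nulls shuffle one region's
trial labels (1000 times at full scale), the observed statistic never
enters the null ensemble, and the suite checks type-I calibration of the
95th-percentile threshold to [0.03, 0.07].

**Relative influence and directionality.** Each direction's Granger
spectrum is divided by its own across-frequency mean (output mean exactly
1), removing signal-to-noise scale differences, and the per-frequency
within-subject difference between directions is tested across subjects.
The published correction is described only as corrected for multiple
comparisons, so the package uses suprathreshold-cluster mass over
contiguous frequencies with a max-cluster sign-flip permutation null — the
standard choice for smooth one-dimensional statistics; a single frequency
degenerates to a paired t-test.

**A note on simulating directed coupling.** Two pitfalls surfaced while
validating the Granger module, and the coupled-source generator is built
to avoid them. First, FFT brick-wall band-limiting is non-causal, so a
"lagged copy" of such a signal carries information about the driver's
future: the driver is instead a strictly causal AR(2) resonator centred in
the requested band. Second, if the driver region observes its own signal
*with* additive noise, the receiver's copy is a second measurement of the
underlying signal and genuinely improves prediction of the driver —
reverse-direction Granger causality is then truly nonzero, not an
estimation artefact. The generator therefore gives the driver region the
band-limited signal itself, and only the receiver carries white noise plus
the lagged, `strength`-scaled copy. With that construction the suite
verifies forward detection against the permutation null and a reverse
direction indistinguishable from it.

## Group statistics

The rank-sum test reports the Mann–Whitney U for the first sample and its
complement $n_1 n_2 - U$, since software conventions differ about which
group's ranks define U. Exact two-sided p-values come from the exact
convolution of the tie-free null (doubling the smaller tail, capped at 1;
sidedness is not otherwise specified); ties fall back to a midrank normal
approximation with tie correction. The association helper reports Pearson
and Spearman coefficients together, the latter's p from the t
approximation. Repeated-measures ANOVA tables are deliberately not
re-implemented: they are standard linear-model machinery, not part of this
package's contribution.

## Pipeline, formats and problem sizes

`run_pipeline()` executes design → simulate → fit → compare → stats →
neural from a YAML `run_config()` in which every stochastic stage has an
explicit derived seed; artefacts are CSV/JSON with an MD5 digest manifest,
and re-running an identical configuration reproduces identical digests.
Neural trial arrays are kept as in-memory matrices and summarised to
CSV/JSON — plain-text formats keep runs portable and diffable.
`vocode()` works on plain numeric waveforms (log-spaced 70–5000 Hz bands,
half-wave-rectified envelopes low-passed at 30 Hz, noise carriers),
leaving audio file I/O to the caller.

Default problem sizes were chosen as the smallest that make the
statistical properties sharp: recovery uses the full 108-trials-per-
condition design across 22 listeners; optimiser validation uses 20
listeners against a 100 × 100 grid; variant comparison uses 50 listeners;
permutation calibration uses 150 replicates of 200 shuffles over 40-trial
sets; latency recovery uses 50 implants. The full-scale choices (1000
shuffles, larger trial counts) remain the documented defaults of the
corresponding functions.

## Known limitations

* The analytic form of the prior weighting function and of the clarity
  normalisation satisfy every stated constraint of the published
  description but are not guaranteed identical to the original
  implementation; fitted parameter *values* are therefore comparable
  within this package, not across implementations.
* No trial-level likelihood or ordinal-regression treatment of ratings,
  and no hierarchical partial pooling across listeners.
* The vocoder is a toy envelope vocoder for testing the degradation
  pipeline, not a speech-quality tool.
* The VAR/Geweke Granger estimator assumes within-window stationarity
  (hence the evoked subtraction) and linear dynamics.
* Schedules model words as bare identifiers; lexical frequency and
  phonological neighbourhood structure are out of scope.
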