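---
title: "Measuring spectrotemporal sensitivity with ripple reaction times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spectrotemporal sensitivity with ripple reaction times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rippleRT)
library(dplyr)
```

## The paradigm

A listener hears ongoing pink noise; at an unpredictable moment a sinusoidal
spectrotemporal modulation — a *ripple* — starts inside a target band, and the
listener responds as fast as possible. The reaction time (RT) from modulation
onset to response indexes how salient that spectrotemporal modulation is to
the listener: conditions a listener resolves well elicit fast responses, while
conditions near the limit of their resolution elicit slow responses or none
within the response window. Because the stimulus is presented well above
detection threshold and the task is a simple change detection, the measure
leans far less on memory and language than speech tests do, which makes it
attractive for cochlear-implant users, where the question "how much
spectrotemporal detail survives the electrode interface?" is directly related
to speech-in-noise outcomes.

`rippleRT` packages the three components such a study needs — the stimulus
engine, a simulator of listeners responding to those stimuli under realistic
delivery conditions, and the statistical analysis chain — so that each stage
can be validated against ground truth before it touches real data.

## Stimulus model

Each trial is built as: pink-noise carrier → band accentuation → ripple
modulation.

* **Carrier.** Seeded white Gaussian noise is shaped in the spectral domain to
  a 1/f power density (−3 dB/octave) and band-passed 0.1–8.7 kHz with a
  first-order Butterworth filter applied once, forward. Spectral-domain
  shaping keeps the carrier exactly reproducible from its seed.
* **Accentuation.** The modulated band (250–8000 Hz broadband, or a 1-octave
  narrowband) is boosted by 15 dB for the whole stimulus duration, with
  raised-cosine (Hanning) transitions 100 Hz wide in linear frequency,
  centered on the band edges (the gain is exactly half the boost at the edge
  frequency). The boost guarantees audibility of the modulated band for
  hearing-impaired listeners.
* **Modulation.** From a randomized onset (0.7–1.2 s in 100 ms steps) the
  short-time spectral amplitude inside the band is multiplied by
  `1 + m·sin(2π[w·(t−t₀) + Ω·log₂(f/f_lo)] + φ₀)` with depth `m = 0.82`,
  rate `w` and density `Ω`. The gain is imposed by an STFT analysis/synthesis
  pair (square-root Hann windows, 75% overlap, 2048 samples ≈ 46 ms at
  44.1 kHz), evaluated at each bin center frequency and frame center time.
  This gives exact control of the joint spectrotemporal gain and perfect
  reconstruction at unity gain. Two consequences are worth knowing:
  the onset transition is smeared over one window (≈ 46 ms) rather than being
  strictly instantaneous, and the overlap-add kernel low-passes the imposed
  temporal modulation — the effective depth at 4 Hz is about 98% of nominal
  (we measure ≈ 80–81% against the nominal 82%), falling further at 16 Hz.
  A shorter window would reduce this loss at the cost of spectral resolution
  for high-density ripples near the low band edge.
* **Ripple drift direction.** With both `w, Ω > 0` the default phase
  convention (`+Ω·log₂(f/f_lo)`) drifts downward; the sign is exposed as
  `omega_sign` because the direction convention is ambiguous in common usage.
  The log-frequency origin sits at the band's lower edge, which makes the
  zero starting phase well defined at `f_lo` and onset time.

**Calibration.** Digital RMS maps to dB SPL through a single reference
(`calibration_model()`: full-scale sinusoid ↦ 105 dB SPL by default, leaving
ample headroom). The carrier's pink-noise density is set so that an ideal
0.1–8.7 kHz pink carrier would integrate to 60 dB SPL; concretely, the
250–8000 Hz band of the unaccented carrier is calibrated to its ideal-pink
share, `60 + 10·log₁₀(log₂32 / log₂87)` ≈ 58.9 dB SPL. Referencing a region
well inside the passband keeps the Butterworth edge losses out of the level
arithmetic, and the accentuated stimuli then land on the closed-form levels:
boosting `k` of `N ≈ 6.44` pink octaves by 15 dB raises the total by
`10·log₁₀((N − k + k·10^1.5)/N)` — +13.9 dB for broadband (74 dB SPL) and
+7.6 dB for narrowband (68 dB SPL). These are properties of the *accentuated
carrier*: while the modulation is on, the in-band level additionally rises by
`10·log₁₀(1 + m²/2)` ≈ 1.3 dB, which is why level checks are made on the
carrier (equivalently, before modulation onset).

The compressor stand-in (`agc_standin()`) is a generic single-band
feed-forward automatic gain control: an RMS tracker drives a capped gain
reduction that engages 400 ms after sound onset, i.e. well before the
earliest modulation onset at 700 ms, so the level is stable when the ripple
starts. It is a documented generic component, not a model of any particular
sound processor, and processor-specific post-compression levels are out of
scope.

## Listener model

The simulator (`simulate_cohort()`) draws trials from the LATER model: a
decision signal rises linearly at a rate drawn per trial from a Gaussian, so
*promptness* (1/RT) is Gaussian with mean `mu_p` and SD `sigma_p`, truncated
to positive rates. We parameterize directly on the promptness scale because
threshold and rise rate are not separately identifiable from RTs. On top of
the deterministic LATER core sit three contaminants: lapses (non-responses,
default 3%), stimulus-independent false positives (homogeneous Poisson
process from noise onset, default 0.02 s⁻¹, racing the LATER unit — the
earliest event within the 3 s window wins), and premature responses (events
before modulation onset), which cause the trial to be regenerated and
counted, mirroring the protocol's trial reiteration. Catch trials carry no
LATER unit: only false positives can produce responses there, which is what
makes them an estimate of false-positive responding.

The study conditions baked into `cohort_config()` defaults: 20 listeners,
two implementations × two blocks × 10 trials of each of the 17 conditions
(680 trials per listener), a fixed 470 ms recording delay for the App-style
implementation, and per-stimulus baseline median RTs spanning 0.5 s (easy
temporally modulated broadband ripples) to 2.0 s (purely spectral
2 cycles/octave), with the narrowband conditions slowing from high to low
center frequency. These reflect the canonical difficulty ordering for
cochlear-implant listeners. A latent sensitivity trait multiplies promptness
(log-linearly, 0.4 per trait SD) for the speech-relevant conditions
(densities 0.25–1 c/o at rates up to 16 Hz, and the 4 kHz narrowband ripple)
and leaves the purely temporal 8 Hz ripple, the 2 c/o ripples and the low-CF
narrowband ripples untouched; the same trait lowers the true
speech-reception threshold by 2 dB per SD (plus 1 dB per SD of z-scored age
and 1 dB of residual noise). This is the ground truth against which the
association analyses are validated: correlations must appear for the loaded
conditions and must not appear for the unloaded ones.

What the generator deliberately does *not* emulate: learning or fatigue
across blocks, age-related motor slowing, express-response limbs, non-Gaussian
promptness, or trial-to-trial delay jitter. Passing tests therefore show the
analysis chain is correct under the stated model, not that real cohorts obey
it.

## Analysis chain

* **Preprocessing** (`preprocess_rt()`): RTs above 2.5 s and non-responses
  are coded *at* 2.5 s with a censored flag; responses faster than 140 ms are
  removed as fast guesses (the floor is exclusive). The delay correction for
  App-recorded RTs is subtracted *before* the ceiling/floor re-check, so a
  corrected response can fall below the floor and be removed. Blocks are
  compared with two-sample Kolmogorov–Smirnov tests and then pooled; the
  median over pooled values (censored codes included) summarizes each cell.
  With an even count the median is the mean of the central pair. Fully
  censored cells are kept at 2.5 s and flagged rather than dropped, so
  downstream analyses can choose.
* **Delay estimation** (`estimate_delay()`): per participant, App − Laptop
  differences of pooled median RTs for three well-perceived reference
  conditions ([4 Hz, 0.5 c/o], [8 Hz, 0 c/o], [16 Hz, 0.25 c/o]); the
  group-level mean is the delay. Group-level (not per-participant)
  subtraction is the default, matching the protocol.
* **Reciprobit / LATER fits** (`fit_later()`): uncensored RTs get Hazen
  plotting positions `(i − 0.5)/n` with `n` counting *all* trials, so misses
  depress the reachable asymptote; censored trials contribute no point. The
  default estimator is a censored maximum-likelihood fit of the
  truncated-at-zero Gaussian promptness model, in which censored trials enter
  through the normal CDF below the ceiling promptness (1/2.5 s⁻¹); `mu_p` is
  log-parameterized so the optimum stays in the valid region. The classic
  least-squares reciprobit line is retained (`method = "ls_line"`); with the
  all-trials plotting convention it is serviceable under moderate censoring,
  but a line fit whose positions ignore censored trials is badly biased,
  which the tests demonstrate explicitly.
* **Estimation statistics** (`bootstrap_mean_diff()`): unpaired bootstrap of
  the difference of means (5000 resamples by default) with a bias-corrected
  and accelerated interval — bias `z₀` from the proportion of bootstrap
  statistics below the estimate, acceleration from jackknife influence
  skewness. The two-sided p-value is the doubled tail probability of zero,
  floored at `2/n_boot`. Implementation differences pool all individual
  trials rather than per-participant medians; censored codes are included in
  means by default (exposed as a flag), as non-detections are part of the
  effect being summarized. Modulation transfer functions (`mtf()`) are
  per-stimulus means with BCa intervals, sliced as iso-velocity and
  iso-density lines; on the promptness scale a separable sensitivity surface
  produces parallel lines, which the tests verify by construction.
* **Speech-in-noise simulation** (`run_adaptive()`): a 5-word matrix-test
  listener with word-correct probability
  `P(snr) = 1/10 + (9/10)·logistic((snr − SRT)/s)`. Both the listener's true
  threshold and the adaptive estimate are defined as the *midpoint* of the
  guess-corrected logistic (P = 0.55 with the 1/10 guessing floor), which
  keeps the recovery unbiased and self-consistent. Tracks start at +10 dB
  SNR; before the maximum-likelihood fit is identifiable the SNR steps −2 dB
  after ≥ 3 correct words and +2 dB otherwise; afterwards each sentence is
  placed at the current ML threshold and the final estimate comes from the
  20-sentence fit. If the fit fails or its binomial deviance exceeds 1.5× its
  degrees of freedom, the mean of the last 8 presented SNRs is used and
  flagged. The step size and deviance criterion are documented stand-ins for
  unpublished procedure details and are configurable.
* **Association** (`spearman_matrix()`, `bayes_pearson_ci()`,
  `fit_srt_regression()`, `fit_hierarchical_rt()`): Spearman correlations
  (midranks) per stimulus with step-down Holm control over the declared
  17-test family; Bayesian 95% credible intervals for Pearson's r on
  promptness from a Metropolis chain on the Fisher z-transform (uniform prior
  on r, 500 burn-in + 1000 kept samples, exact marginal likelihood given the
  sample correlation); the threshold regression
  `SRT = β₀ + β₁·z(Age) + β₂·z(Pr) + β₃·z(Age)·z(Pr)` with an optional
  p-value stepwise search (enter 0.05, remove 0.10 — common defaults, as the
  selection criteria are procedure names rather than published thresholds);
  and a Bayesian censored regression of log-RT on implementation, stimulus
  and participant with all first-order interactions (sum-to-zero contrasts),
  sampled by a data-augmentation Gibbs sampler that imputes censored log-RTs
  from the truncated normal above log(2.5) each sweep, with weakly
  informative Normal(0, 2.5²) coefficient priors and an inverse-gamma
  variance prior. The log-normal likelihood is a standard choice for
  censored RT regression; its location estimates agree with the
  reciprocal-normal LATER fit at the few-percent level on the median-RT
  scale, which the tests check.

## Numerical choices and degenerate inputs

Estimation failures are flagged, not thrown: a non-convergent LATER fit
falls back to moment estimates with `converged = FALSE`; an unidentifiable
psychometric fit triggers the mean-of-last-8 fallback; constant bootstrap
samples return a degenerate interval with a warning; constant SRT vectors
mark the correlation cell undefined; perfect correlations are kept proper by
capping |Fisher z| at 8. Every stochastic function takes a `seed` and
restores the caller's RNG state; one root seed spawns independent
per-listener streams.

## Problem sizes in the validation suite

The test suite validates each claim at sizes chosen to keep Monte-Carlo
error comfortably inside the asserted tolerances: 500 replicates for the
censored-MLE recovery (n = 20 trials, ~30% censoring) and for the adaptive
threshold bias; 1000 replicates for BCa coverage (n = 40 per group, 1000
resamples) and for the Holm family-wise error simulation (17 tests, n = 19);
a 20-listener cohort for the delay-recovery and end-to-end correlation
pattern checks. Acoustic measurements use 10–12 s realizations, long enough
that Welch-PSD and level estimates sit an order of magnitude inside the
±0.5–1 dB tolerances.

## Known limitations

* The STFT gain approach smears the modulation onset by one analysis window
  and attenuates high modulation rates (see above); studies centered on
  16+ Hz rates should shorten the window or apply the temporal factor in the
  time domain.
* The LATER fit models a single decision limb; express responses are assumed
  to have been removed by the 140 ms floor.
* The hierarchical model treats effects as fixed with shared shrinkage
  rather than as nested random effects; for the balanced designs simulated
  here the two parameterizations give equivalent cell means.
* The adaptive speech-test rules (step size, fit-error criterion) are
  plausible stand-ins, configurable but not validated against any specific
  clinical implementation.
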