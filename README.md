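# rippleRT

Reaction times to the onset of a spectrotemporal modulation are a fast,
cognitively undemanding probe of auditory spectrotemporal sensitivity —
particularly useful for cochlear-implant users, whose speech-in-noise
performance depends on how well they resolve spectral and temporal
modulations. `rippleRT` implements that paradigm end to end for
psychoacousticians and audiology researchers:

* **Stimulus synthesis.** Calibrated ripple-in-noise stimuli: a pink-noise
  carrier (0.1–8.7 kHz, first-order Butterworth edges) whose modulated band is
  accentuated by 15 dB (Hanning-smoothed edges) and then multiplied, on a
  linear amplitude scale, by the spectrotemporal gain

  `g(f, t) = 1 + m · sin(2π [ w·(t − t₀) + Ω·log₂(f / f_lo) ] + φ₀)`

  with rate `w` (Hz), density `Ω` (cycles/octave) and depth `m = 0.82`.
  The canonical set has 17 conditions (12 modulated broadband, 4 one-octave
  narrowband, 1 unmodulated catch), synthesized to WAV with JSON sidecars.
* **Listener simulation.** Cohorts of LATER-model listeners: promptness
  (1/RT) is Gaussian per listener × stimulus; a latent
  spectrotemporal-sensitivity trait drives both ripple promptness and the
  speech-reception threshold (SRT); false positives race the decision as a
  Poisson process; App-style delivery adds a fixed technical delay.
* **Analysis.** The full reaction-time chain: censoring at 2.5 s,
  fast-guess removal below 140 ms, block pooling with Kolmogorov–Smirnov
  checks, three-stimulus delay alignment, censoring-aware LATER fits on
  reciprobit coordinates, BCa-bootstrapped effect sizes, modulation transfer
  functions, adaptive matrix speech-in-noise simulation, and Spearman /
  Bayesian-Pearson / regression analyses linking promptness to SRT.

## Worked example

```r
library(rippleRT)
library(dplyr)

# one calibrated broadband ripple (4 Hz, 0.5 cycles/octave)
cal  <- calibration_model()
spec <- ripple_spec("broadband", omega = 0.5, rate_hz = 4)
aud  <- assemble_trial(spec, cal, seed = 1)
measure_level_dbspl(aud, cal, window = c(0, aud$onset_s))
#> [1] 73.91886   # accentuated carrier before modulation onset (74 dB SPL nominal)

# a 20-listener cohort under both implementations, analyzed end to end
sim  <- simulate_cohort(cohort_config(), seed = 308)
pipe <- rt_pipeline(sim$trials)
pipe$delay
#> <delay_estimate> 471.0 ms (mean of 60 participant x stimulus differences)

srt   <- simulate_srt(sim$profiles, seed = 309)
cells <- spearman_matrix(filter(pipe$medians, implementation == "Laptop"),
                         srt, family_size = 17, seed = 310)
cells |> filter(holm_significant) |> select(stimulus_id, r_spearman, p_raw)
#> # A tibble: 2 × 3
#>   stimulus_id  r_spearman    p_raw
#>   <chr>             <dbl>    <dbl>
#> 1 bb_0Hz_0.5co      0.719 0.000520
#> 2 bb_8Hz_1co        0.671 0.00161
```

The delay estimate recovers the configured 470 ms App/Laptop technical
offset from the three well-perceived reference stimuli; the correlation
cells show which ripple conditions' median reaction times track the
speech-reception threshold, with Holm–Bonferroni control over the 17-test
family (`autoplot()` and `plot_correlation_heatmap()` draw the standard
figures).

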