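#' Generate a band-passed pink-noise carrier
#'
#' Seeded white Gaussian noise is shaped in the spectral domain (amplitude
#' proportional to `1/sqrt(f)`, i.e. a power density falling 3 dB/octave) and
#' then band-passed once, forward (causal), with a first-order Butterworth
#' filter.
#'
#' @param duration_s carrier duration in seconds.
#' @param sample_rate_hz sampling rate in Hz (default 44100).
#' @param band band edges in Hz (default 100--8700).
#' @param seed integer seed; the same seed gives a bit-identical carrier.
#' @return a [trial_audio()] with unit-RMS-order samples (uncalibrated).
#' @export
make_pink_noise <- function(duration_s, sample_rate_hz = 44100,
                            band = c(100, 8700), seed = NULL) {
  assert_scalar_num_(duration_s, "duration_s", lower = 1e-6)
  if (max(band) >= sample_rate_hz / 2) {
    abort("band edge at or above Nyquist", class = "rippleRT_invalid_configuration")
  }
  n <- round(duration_s * sample_rate_hz)
  white <- with_seed_(seed, rnorm(n))
  X <- fft(white)
  f <- (seq_len(n) - 1) * sample_rate_hz / n
  f_fold <- pmin(f, sample_rate_hz - f)
  shape <- ifelse(f_fold < 1, 0, 1 / sqrt(f_fold)) # kill DC, pink elsewhere
  x <- Re(fft(X * shape, inverse = TRUE)) / n
  bf <- signal::butter(1, band / (sample_rate_hz / 2), type = "pass")
  x <- as.numeric(signal::filter(bf, x))
  x <- x / sd(x) * 0.02 # nominal working level well below full scale
  trial_audio(x, sample_rate_hz, noise_seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Apply sinusoidal spectrotemporal modulation
#'
#' From `onset_s` onwards, and within the spec's modulated band, each
#' short-time spectral amplitude is multiplied on a linear amplitude scale by
#' `g(f, t) = 1 + depth * sin(2*pi*(rate*(t - onset) + sign*omega*log2(f/f_lo)) + phase0)`.
#' Gain is unity before onset and outside the band, and the transition at
#' onset is not ramped. The gain is imposed by a short-time Fourier
#' analysis/synthesis (square-root Hann windows, 75% overlap, approximately
#' 46 ms at 44.1 kHz), evaluated at each bin's center frequency and each
#' frame's center time.
#'
#' @param carrier a [trial_audio()].
#' @param spec a [ripple_spec()].
#' @param onset_s modulation onset in seconds from the start of the carrier.
#' @param mod_duration_s maximum modulated duration in seconds (gain returns
#'   to unity afterwards); `Inf` modulates to the end of the carrier.
#' @param nfft STFT size in samples (2048 at 44.1 kHz is about 46 ms).
#' @return a [trial_audio()] with `onset_s` and `spec` recorded.
#' @export
apply_stm <- function(carrier, spec, onset_s, mod_duration_s = Inf, nfft = 2048L) {
  stopifnot(inherits(carrier, "trial_audio"), inherits(spec, "ripple_spec"))
  if (spec$depth > 1) {
    abort("modulation depth above 1 would gate the signal negative",
          class = "rippleRT_invalid_configuration")
  }
  if (is.finite(mod_duration_s) && onset_s + mod_duration_s > carrier$total_duration_s + 1e-9) {
    abort("onset_s + mod_duration_s exceeds the carrier duration",
          class = "rippleRT_invalid_configuration")
  }
  sr <- carrier$sample_rate_hz
  st <- stft_(carrier$samples, nfft = nfft)
  tc <- stft_times_(st, sr)
  fc <- stft_freqs_(st, sr)
  in_band <- fc >= spec$f_lo & fc <= spec$f_hi
  t_end <- if (is.finite(mod_duration_s)) onset_s + mod_duration_s else Inf
  in_time <- tc >= onset_s & tc <= t_end
  gain <- matrix(1, nrow = length(fc), ncol = length(tc))
  if (any(in_band) && any(in_time) && spec$depth > 0) {
    xf <- spec$omega_sign * spec$omega * log2(fc[in_band] / spec$f_lo)
    phase <- outer(2 * pi * xf, 2 * pi * spec$rate_hz * (tc[in_time] - onset_s), "+") +
      spec$phase0
    gain[in_band, in_time] <- 1 + spec$depth * sin(phase)
  }
  y <- istft_(stft_apply_gain_(st, gain))
  trial_audio(y, sr, onset_s = onset_s, spec = spec, noise_seed = carrier$noise_seed)
}

# uniform draw from the protocol onset grid (0.7..1.2 s in 100 ms steps)
draw_onset_ <- function(seed) {
  with_seed_(seed, sample(seq(0.7, 1.2, by = 0.1), 1))
}

# raised-cosine band gain profile in linear frequency; +accent_db inside the
# band, 0 dB outside, Hanning transitions of width edge_width_hz centered on
# each edge (gain is accent_db/2 exactly at the edge frequency)
accent_gain_db_ <- function(f, f_lo, f_hi, accent_db, edge_width_hz) {
  w <- edge_width_hz
  g <- numeric(length(f))
  ramp_up <- f > (f_lo - w / 2) & f < (f_lo + w / 2)
  ramp_dn <- f > (f_hi - w / 2) & f < (f_hi + w / 2)
  inside <- f >= (f_lo + w / 2) & f <= (f_hi - w / 2)
  g[inside] <- accent_db
  g[ramp_up] <- accent_db * (0.5 - 0.5 * cos(pi * (f[ramp_up] - (f_lo - w / 2)) / w))
  g[ramp_dn] <- accent_db * (0.5 + 0.5 * cos(pi * (f[ramp_dn] - (f_hi - w / 2)) / w))
  g
}

#' Accentuate the modulated band
#'
#' Boosts the modulated band by `accent_db` for the full stimulus duration,
#' with gain transitions following a raised-cosine (Hanning) profile of width
#' `edge_width_hz` in linear frequency, centered on the band edges. Applied as
#' a zero-phase spectral gain over the whole buffer.
#'
#' @param buffer a [trial_audio()].
#' @param f_lo,f_hi band edges in Hz.
#' @param accent_db boost in dB (default 15).
#' @param edge_width_hz Hanning transition width in Hz (default 100).
#' @return a [trial_audio()].
#' @export
apply_accentuation <- function(buffer, f_lo, f_hi, accent_db = 15,
                               edge_width_hz = 100) {
  stopifnot(inherits(buffer, "trial_audio"))
  if (f_lo >= f_hi) abort("f_lo must be below f_hi", class = "rippleRT_invalid_configuration")
  if (f_hi - f_lo < edge_width_hz) {
    abort("band narrower than the edge transition width",
          class = "rippleRT_invalid_configuration")
  }
  x <- buffer$samples
  n <- length(x)
  sr <- buffer$sample_rate_hz
  f <- (seq_len(n) - 1) * sr / n
  f_fold <- pmin(f, sr - f)
  gain <- db_to_amp_(accent_gain_db_(f_fold, f_lo, f_hi, accent_db, edge_width_hz))
  y <- Re(fft(fft(x) * gain, inverse = TRUE)) / n
  out <- buffer
  out$samples <- y
  out
}

#' Single-band feed-forward compressor stand-in
#'
#' A documented generic stand-in for sound-processor automatic gain control:
#' after an engagement delay, the gain decays exponentially toward a
#' steady-state reduction determined by the input level above an internal
#' threshold. The envelope is tracked with a one-pole smoother, so the
#' compressor reacts to the signal itself; with the canonical stimuli the
#' level is stable well before the earliest modulation onset (0.7 s > 0.4 s
#' engagement).
#'
#' @param buffer a [trial_audio()].
#' @param attack_delay_s engagement delay after sound onset (default 0.4 s).
#' @param gain_reduction_db steady-state gain reduction in dB.
#' @param tau_s time constant of the gain trajectory and envelope smoother.
#' @return a [trial_audio()].
#' @export
agc_standin <- function(buffer, attack_delay_s = 0.4, gain_reduction_db = 0,
                        tau_s = 0.05) {
  stopifnot(inherits(buffer, "trial_audio"))
  assert_scalar_num_(attack_delay_s, "attack_delay_s", lower = 0)
  if (gain_reduction_db == 0) return(buffer)
  x <- buffer$samples
  sr <- buffer$sample_rate_hz
  n <- length(x)
  # one-pole envelope of the squared signal (RMS tracker); the level estimate
  # is smoothed over a longer window than the gain trajectory so the static
  # gain does not chatter with the carrier's own envelope fluctuations
  alpha <- exp(-1 / (4 * tau_s * sr))
  env2 <- as.numeric(signal::filter(c(1 - alpha), c(1, -alpha), x^2))
  ref2 <- mean(x[seq_len(min(n, round(0.3 * sr)))]^2) # pre-engagement level
  # reduction proportional to instantaneous level re. the pre-engagement
  # reference, capped at the configured steady-state reduction
  red_db <- pmin(gain_reduction_db,
                 pmax(0, gain_reduction_db + 10 * log10(pmax(env2, 1e-20) / ref2)))
  t <- (seq_len(n) - 1) / sr
  engage <- pmax(0, 1 - exp(-(t - attack_delay_s) / tau_s)) * (t >= attack_delay_s)
  gain <- db_to_amp_(-red_db * engage)
  out <- buffer
  out$samples <- x * gain
  out
}

#' Assemble a complete calibrated ripple trial
#'
#' Full synthesis pipeline: seeded pink-noise carrier (0.1--8.7 kHz), carrier
#' calibrated so the unaccented noise sits at `noise_dbspl` (the level of the
#' noise outside the modulated band), band accentuation for the full duration,
#' then sinusoidal spectrotemporal modulation from a randomized onset. The
#' onset is drawn uniformly from `{0.7, 0.8, 0.9, 1.0, 1.1, 1.2}` s unless
#' given explicitly.
#'
#' @param spec a [ripple_spec()].
#' @param calibration a [calibration_model()].
#' @param seed integer seed driving both the onset draw and the noise carrier.
#' @param onset_s fixed onset in seconds, or `NULL` to randomize.
#' @param mod_duration_s modulated duration (protocol default 3 s).
#' @param noise_dbspl presentation level of the unaccented carrier (60 dB SPL).
#' @param sample_rate_hz sampling rate.
#' @param modulate set `FALSE` to stop after accentuation (the accentuated
#'   carrier every trial presents before modulation onset).
#' @param agc_gain_reduction_db if nonzero, apply [agc_standin()] with this
#'   steady-state reduction after calibration.
#' @return a [trial_audio()] with onset, spec and seed metadata.
#' @export
assemble_trial <- function(spec, calibration = calibration_model(), seed = NULL,
                           onset_s = NULL, mod_duration_s = 3,
                           noise_dbspl = 60, sample_rate_hz = 44100,
                           modulate = TRUE, agc_gain_reduction_db = 0) {
  stopifnot(inherits(spec, "ripple_spec"))
  seeds <- spawn_seeds_(seed %||% sample.int(1e7, 1), 2)
  if (is.null(onset_s)) onset_s <- draw_onset_(seeds[1])
  duration_s <- onset_s + mod_duration_s
  carrier <- make_pink_noise(duration_s, sample_rate_hz, seed = seeds[2])
  # Calibrate via the pink-noise spectral density: the 250-8000 Hz band of the
  # unaccented carrier is set to its ideal-pink share of a `noise_dbspl`
  # 0.1-8.7 kHz carrier (band level = noise_dbspl + 10*log10(5/6.44) dB).
  # Referencing a region well inside the passband keeps the first-order
  # Butterworth edge losses out of the level arithmetic.
  ref_level <- noise_dbspl + 10 * log10(log2(8000 / 250) / log2(8700 / 100))
  band_level <- measure_level_dbspl(carrier, calibration, band = c(250, 8000))
  carrier$samples <- carrier$samples * db_to_amp_(ref_level - band_level)
  out <- apply_accentuation(carrier, spec$f_lo, spec$f_hi, spec$accent_db)
  if (agc_gain_reduction_db != 0) {
    out <- agc_standin(out, gain_reduction_db = agc_gain_reduction_db)
  }
  if (modulate && spec$band_kind != "catch" && spec$depth > 0 &&
      (spec$rate_hz > 0 || spec$omega > 0)) {
    out <- apply_stm(out, spec, onset_s, mod_duration_s)
  } else {
    out$onset_s <- onset_s
    out$spec <- spec
  }
  out$noise_seed <- seeds[2]
  if (any(abs(out$samples) > 1)) {
    abort("calibration leaves no headroom: samples clip beyond full scale",
          class = "rippleRT_invalid_configuration")
  }
  out
}

#' Synthesize the full canonical stimulus set to WAV files
#'
#' Renders every condition of [stimulus_table()] to a PCM16 WAV plus a JSON
#' sidecar recording the spec, onset, seed and calibration.
#'
#' @param out_dir output directory (created if needed).
#' @param seed root seed; each condition gets an independent child seed.
#' @param calibration a [calibration_model()].
#' @param sample_rate_hz sampling rate.
#' @return invisibly, a tibble of written file paths and trial metadata.
#' @export
synthesize_stimulus_set <- function(out_dir, seed = 1,
                                    calibration = calibration_model(),
                                    sample_rate_hz = 44100) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- stimulus_table()
  seeds <- spawn_seeds_(seed, nrow(tab))
  meta <- purrr::map2(tab$spec, seeds, function(spec, s) {
    audio <- assemble_trial(spec, calibration, seed = s,
                            sample_rate_hz = sample_rate_hz)
    base <- file.path(out_dir, spec_id_(spec))
    write_wav(audio, paste0(base, ".wav"))
    side <- list(spec = unclass(spec), onset_s = audio$onset_s, seed = s,
                 dbspl_at_fullscale = calibration$dbspl_at_fullscale)
    jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
    tibble::tibble(stimulus_id = spec_id_(spec), wav = paste0(base, ".wav"),
                   onset_s = audio$onset_s, seed = s)
  })
  invisible(dplyr::bind_rows(meta))
}
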