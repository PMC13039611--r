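#' Audio buffer for one stimulus
#'
#' Lightweight container for a mono audio buffer: dimensionless samples on a
#' full-scale +/-1 convention, plus metadata about the stimulus it realizes.
#'
#' @param samples numeric vector of samples.
#' @param sample_rate_hz sampling rate in Hz.
#' @param onset_s modulation onset in seconds (`NA` if not applicable).
#' @param spec the [ripple_spec()] realized, or `NULL`.
#' @param noise_seed integer seed used for the noise carrier, or `NA`.
#' @return an object of class `trial_audio`.
#' @export
trial_audio <- function(samples, sample_rate_hz, onset_s = NA_real_,
                        spec = NULL, noise_seed = NA_integer_) {
  stopifnot(is.numeric(samples), length(samples) > 0)
  assert_scalar_num_(sample_rate_hz, "sample_rate_hz", lower = 1)
  structure(
    list(samples = as.numeric(samples),
         sample_rate_hz = sample_rate_hz,
         onset_s = onset_s,
         total_duration_s = length(samples) / sample_rate_hz,
         spec = spec,
         noise_seed = noise_seed),
    class = "trial_audio"
  )
}

#' @export
print.trial_audio <- function(x, ...) {
  cat(sprintf("<trial_audio> %.3f s @ %g Hz, onset %s s, rms %.4g\n",
              x$total_duration_s, x$sample_rate_hz,
              ifelse(is.na(x$onset_s), "-", format(x$onset_s)),
              sqrt(mean(x$samples^2))))
  invisible(x)
}

#' Map digital RMS to sound pressure level
#'
#' The calibration convention maps a full-scale sinusoid (RMS `1/sqrt(2)`)
#' to `dbspl_at_fullscale` dB SPL; any other RMS is scaled relative to it.
#'
#' @param dbspl_at_fullscale dB SPL produced by a full-scale sinusoid.
#'   The default leaves comfortable headroom above the canonical 60--74 dB SPL
#'   presentation levels.
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(dbspl_at_fullscale = 105) {
  assert_scalar_num_(dbspl_at_fullscale, "dbspl_at_fullscale")
  structure(list(dbspl_at_fullscale = dbspl_at_fullscale),
            class = "calibration_model")
}

rms_to_dbspl_ <- function(rms, calibration) {
  calibration$dbspl_at_fullscale + 20 * log10(rms * sqrt(2))
}

dbspl_to_rms_ <- function(dbspl, calibration) {
  10^((dbspl - calibration$dbspl_at_fullscale) / 20) / sqrt(2)
}

# zero-phase band-pass via FFT masking (brick wall); used for measurement only
fft_bandpass_ <- function(x, sr, f_lo, f_hi) {
  n <- length(x)
  X <- fft(x)
  f <- (seq_len(n) - 1) * sr / n
  f <- pmin(f, sr - f) # fold to 0..Nyquist
  keep <- f >= f_lo & f <= f_hi
  Re(fft(X * keep, inverse = TRUE)) / n
}

#' Measure the level of an audio buffer in dB SPL
#'
#' RMS level over a time window, optionally band-limited (zero-phase FFT
#' brick-wall filter), mapped through the calibration model.
#'
#' @param buffer a [trial_audio()].
#' @param calibration a [calibration_model()].
#' @param window numeric length-2 `(t0, t1)` in seconds; default whole buffer.
#' @param band optional length-2 Hz range to band-limit before measuring.
#' @return level in dB SPL (scalar).
#' @export
measure_level_dbspl <- function(buffer, calibration = calibration_model(),
                                window = NULL, band = NULL) {
  stopifnot(inherits(buffer, "trial_audio"), inherits(calibration, "calibration_model"))
  x <- buffer$samples
  sr <- buffer$sample_rate_hz
  if (!is.null(band)) x <- fft_bandpass_(x, sr, band[1], band[2])
  if (!is.null(window)) {
    i0 <- max(1L, floor(window[1] * sr) + 1L)
    i1 <- min(length(x), floor(window[2] * sr))
    if (i1 < i0) {
      abort("empty measurement window", class = "rippleRT_invalid_argument")
    }
    x <- x[i0:i1]
  }
  rms_to_dbspl_(sqrt(mean(x^2)), calibration)
}

#' Welch power spectral density
#'
#' Averaged-periodogram (Welch) PSD estimate with a Hann window and 50%
#' overlap; used to verify the acoustic properties of synthesized stimuli.
#'
#' @param x numeric samples or a [trial_audio()].
#' @param sample_rate_hz sampling rate (ignored when `x` is a `trial_audio`).
#' @param nfft segment length (power of two recommended).
#' @return tibble with `freq_hz` and `psd` (power per Hz, one-sided).
#' @export
welch_psd <- function(x, sample_rate_hz = NULL, nfft = 8192) {
  if (inherits(x, "trial_audio")) {
    sample_rate_hz <- x$sample_rate_hz
    x <- x$samples
  }
  stopifnot(!is.null(sample_rate_hz), length(x) >= nfft)
  hop <- nfft %/% 2
  n_seg <- (length(x) - nfft) %/% hop + 1L
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1)) / nfft)
  idx <- outer(0:(nfft - 1), (0:(n_seg - 1)) * hop, "+") + 1L
  seg <- matrix(x[idx], nrow = nfft) * w
  P <- abs(stats::mvfft(seg))^2
  scale <- 1 / (sample_rate_hz * sum(w^2))
  pxx <- rowMeans(P) * scale
  half <- 1:(nfft %/% 2 + 1)
  pxx <- pxx[half]
  pxx[2:(length(pxx) - 1)] <- 2 * pxx[2:(length(pxx) - 1)] # one-sided
  tibble::tibble(freq_hz = (half - 1) * sample_rate_hz / nfft, psd = pxx)
}

# analytic-signal magnitude via FFT (Hilbert envelope)
hilbert_envelope_ <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Recover modulation depth from the band-limited envelope
#'
#' Estimates the effective temporal modulation depth of a synthesized ripple:
#' band-limits the signal to the modulated band, takes the Hilbert envelope of
#' the modulated segment, averages it over modulation periods, and returns
#' `(max - min) / (max + min)` of the period-averaged envelope. For a gain
#' `1 + m*sin(2*pi*rate*t)` this recovers `m`.
#'
#' @param buffer a [trial_audio()] carrying its `spec` and `onset_s`, or any
#'   buffer with the remaining arguments supplied.
#' @param rate_hz modulation rate; defaults to the spec's rate.
#' @param band modulated band `(f_lo, f_hi)` in Hz; defaults to the spec's.
#' @param onset_s modulation onset; defaults to the buffer's.
#' @param n_bins phase bins per modulation period for the period average.
#' @return modulation depth as a fraction in `[0, 1]`.
#' @export
measure_modulation_depth <- function(buffer, rate_hz = NULL, band = NULL,
                                     onset_s = NULL, n_bins = 64) {
  stopifnot(inherits(buffer, "trial_audio"))
  spec <- buffer$spec
  rate_hz <- rate_hz %||% spec$rate_hz
  band <- band %||% c(spec$f_lo, spec$f_hi)
  onset_s <- onset_s %||% buffer$onset_s
  stopifnot(rate_hz > 0)
  sr <- buffer$sample_rate_hz
  xb <- fft_bandpass_(buffer$samples, sr, band[1], band[2])
  env <- hilbert_envelope_(xb)
  # whole modulation periods strictly after onset
  i0 <- floor(onset_s * sr) + 1L
  n_per <- floor((length(env) - i0 + 1L) / (sr / rate_hz))
  i1 <- i0 + floor(n_per * sr / rate_hz) - 1L
  env <- env[i0:i1]
  t <- (seq_along(env) - 1) / sr
  phase_bin <- floor(((t * rate_hz) %% 1) * n_bins) %% n_bins
  folded <- tapply(env, phase_bin, mean)
  (max(folded) - min(folded)) / (max(folded) + min(folded))
}

#' Write / read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer and reader for distributing synthesized stimuli.
#' Samples are expected in `[-1, 1]`; values outside are clipped with a
#' warning.
#'
#' @param buffer a [trial_audio()].
#' @param path file path.
#' @return `write_wav()` returns `path` invisibly; `read_wav()` a
#'   [trial_audio()].
#' @export
write_wav <- function(buffer, path) {
  stopifnot(inherits(buffer, "trial_audio"))
  x <- buffer$samples
  if (any(abs(x) > 1)) {
    warn("samples clipped to +/-1 when writing WAV")
    x <- pmin(1, pmax(-1, x))
  }
  sr <- as.integer(round(buffer$sample_rate_hz))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  stopifnot(hdr == "RIFF")
  readBin(con, "integer", 1, size = 4, endian = "little")
  stopifnot(readChar(con, 4) == "WAVE")
  sr <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) abort("no data chunk found")
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      stopifnot(fmt[1] == 1, fmt[2] == 1)
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "raw", sz - 8)
    } else if (id == "data") {
      pcm <- readBin(con, "integer", sz / 2, size = 2, endian = "little")
      break
    } else {
      readBin(con, "raw", sz)
    }
  }
  trial_audio(pcm / 32767, sr)
}
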