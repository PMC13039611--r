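# Short-time Fourier analysis/synthesis with square-root Hann windows and 75%
# overlap. With unity gain the pipeline reconstructs the input exactly (up to
# edge frames), because the squared sqrt-Hann windows overlap-add to a
# constant (COLA at hop = nfft/4).

stft_ <- function(x, nfft = 2048L, hop = nfft %/% 4L) {
  n <- length(x)
  w <- sqrt(0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1)) / nfft))
  # pad so every sample is covered by full frames
  pad <- nfft
  xp <- c(numeric(pad), x, numeric(pad + nfft))
  n_frames <- (length(xp) - nfft) %/% hop + 1L
  idx <- outer(0:(nfft - 1), (0:(n_frames - 1)) * hop, "+") + 1L
  frames <- matrix(xp[idx], nrow = nfft) * w
  list(S = stats::mvfft(frames), nfft = nfft, hop = hop, pad = pad, n = n,
       window = w)
}

istft_ <- function(st) {
  nfft <- st$nfft; hop <- st$hop
  frames <- Re(stats::mvfft(st$S, inverse = TRUE)) / nfft
  frames <- frames * st$window
  n_frames <- ncol(frames)
  out <- numeric((n_frames - 1L) * hop + nfft)
  for (k in seq_len(n_frames)) {
    i <- (k - 1L) * hop
    out[(i + 1):(i + nfft)] <- out[(i + 1):(i + nfft)] + frames[, k]
  }
  # squared sqrt-Hann windows at 75% overlap sum to nfft/(2*hop) = 2
  out <- out / (nfft / (2 * hop))
  out[(st$pad + 1):(st$pad + st$n)]
}

# frame center times (s) relative to the start of the original signal
stft_times_ <- function(st, sample_rate_hz) {
  n_frames <- ncol(st$S)
  ((0:(n_frames - 1)) * st$hop + st$nfft / 2 - st$pad) / sample_rate_hz
}

# bin center frequencies for the first nfft/2+1 bins
stft_freqs_ <- function(st, sample_rate_hz) {
  (0:(st$nfft %/% 2)) * sample_rate_hz / st$nfft
}

# multiply the spectrogram by a real gain matrix defined over the positive
# half spectrum (nfft/2+1 x n_frames), preserving conjugate symmetry
stft_apply_gain_ <- function(st, gain_half) {
  nfft <- st$nfft
  full <- rbind(gain_half, gain_half[(nfft %/% 2):2, , drop = FALSE])
  st$S <- st$S * full
  st
}
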