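# stimulus specification and table -------------------------------------------

test_that("canonical stimulus table matches the protocol grid", {
  tab <- stimulus_table()
  expect_equal(nrow(tab), 17)
  expect_equal(sum(tab$band_kind == "catch"), 1)
  nb <- dplyr::filter(tab, band_kind == "narrowband")
  expect_equal(sort(nb$cf_hz), c(500, 1000, 2000, 4000))
  expect_true(all(nb$omega == 2 & nb$rate_hz == 4))
  expect_true(all(abs(nb$f_hi / nb$f_lo - 2) < 1e-9))
  bb <- dplyr::filter(tab, band_kind == "broadband")
  expect_equal(nrow(bb), 12)
  expect_equal(anyDuplicated(tab$stimulus_id), 0)
  catch <- tab$spec[tab$band_kind == "catch"][[1]]
  expect_equal(catch$omega, 0)
  expect_equal(catch$rate_hz, 0)
})

test_that("invalid ripple specs are rejected", {
  expect_error(ripple_spec("broadband", depth = 1.2),
               class = "rippleRT_invalid_configuration")
  expect_error(ripple_spec("catch", omega = 1),
               class = "rippleRT_invalid_configuration")
  expect_error(ripple_spec("narrowband", f_lo = 500, f_hi = 1200),
               class = "rippleRT_invalid_configuration")
})

# pink noise ------------------------------------------------------------------

test_that("pink noise is deterministic and has a -3 dB/octave spectrum", {
  a <- make_pink_noise(2, seed = 1)
  b <- make_pink_noise(2, seed = 1)
  expect_identical(a$samples, b$samples)
  expect_error(make_pink_noise(1, sample_rate_hz = 16000, band = c(100, 8700)),
               class = "rippleRT_invalid_configuration")

  long <- make_pink_noise(30, seed = 2)
  psd <- welch_psd(long)
  # compensate the documented first-order Butterworth band edges so the fit
  # isolates the pink (1/f) shaping itself
  h2 <- 1 / (1 + (100 / psd$freq_hz)^2) / (1 + (psd$freq_hz / 8700)^2)
  pink <- psd$psd / h2
  sel <- psd$freq_hz >= 300 & psd$freq_hz <= 6000
  fit <- lm(db ~ oct, data = data.frame(db = 10 * log10(pink[sel]),
                                        oct = log2(psd$freq_hz[sel])))
  expect_equal(unname(coef(fit)["oct"]), -3, tolerance = 0.3 / 3)

  # octave-counting: power in 250-8000 Hz over 100-8700 Hz ~ log(32)/log(87)
  p_in <- sum(pink[psd$freq_hz >= 250 & psd$freq_hz <= 8000])
  p_all <- sum(pink[psd$freq_hz >= 100 & psd$freq_hz <= 8700])
  expect_equal(p_in / p_all, log(32) / log(87), tolerance = 0.03 / 0.776)
})

# spectrotemporal modulation --------------------------------------------------

test_that("zero-depth modulation reconstructs the carrier", {
  carrier <- make_pink_noise(3, seed = 3)
  spec <- ripple_spec("broadband", omega = 0.5, rate_hz = 4, depth = 0)
  out <- apply_stm(carrier, spec, onset_s = 1)
  resid <- out$samples - carrier$samples
  # residual at least 40 dB below the signal
  expect_lt(10 * log10(mean(resid^2) / mean(carrier$samples^2)), -40)
})

test_that("temporal-only ripple produces a periodic envelope at the rate", {
  spec <- ripple_spec("broadband", omega = 0, rate_hz = 4)
  aud <- assemble_trial(spec, fixture_cal, seed = 4, onset_s = 1,
                        mod_duration_s = 8)
  # dominant envelope frequency of the band-limited modulated segment
  xb <- aud$samples
  sr <- aud$sample_rate_hz
  env <- abs(xb)
  i0 <- sr * 1 + 1
  env <- env[i0:length(env)] - mean(env[i0:length(env)])
  n <- length(env)
  spec_env <- Mod(fft(env))[1:(n %/% 2)]
  freqs <- (0:(n %/% 2 - 1)) / (n / sr)
  cand <- freqs > 0.5 & freqs < 30
  expect_equal(freqs[cand][which.max(spec_env[cand])], 4, tolerance = 0.05 / 4)
})

test_that("spectral-only ripple imprints the configured density on the spectrum", {
  spec <- ripple_spec("broadband", omega = 0.5, rate_hz = 0, accent_db = 0)
  carrier <- make_pink_noise(20, seed = 5)
  out <- apply_stm(carrier, spec, onset_s = 0.5)
  psd <- welch_psd(out, nfft = 16384)
  sel <- psd$freq_hz >= 300 & psd$freq_hz <= 7000
  oct <- log2(psd$freq_hz[sel] / spec$f_lo)
  prof <- 10 * log10(psd$psd[sel] * psd$freq_hz[sel]) # pink-compensated
  # fit a sinusoid in log2 frequency at the nominal density and nearby ones;
  # the nominal one must explain the most variance
  r2_at <- function(om) {
    summary(lm(prof ~ sin(2 * pi * om * oct) + cos(2 * pi * om * oct)))$r.squared
  }
  dens <- seq(0.3, 0.7, by = 0.02)
  best <- dens[which.max(vapply(dens, r2_at, 0))]
  expect_equal(best, 0.5, tolerance = 0.03 / 0.5)
})

# accentuation ----------------------------------------------------------------

test_that("accentuation boosts the band by the configured gain with Hanning edges", {
  aud <- fixture_nb_carrier()
  psd <- welch_psd(aud)
  h2 <- 1 / (1 + (100 / psd$freq_hz)^2) / (1 + (psd$freq_hz / 8700)^2)
  comp <- 10 * log10(psd$psd * psd$freq_hz / h2) # carrier-shape compensated
  in_band <- mean(comp[psd$freq_hz >= 800 & psd$freq_hz <= 1200])
  out_band <- mean(comp[psd$freq_hz >= 2000 & psd$freq_hz <= 6000])
  expect_equal(in_band - out_band, 15, tolerance = 1 / 15)

  # gain at the exact band edge is half the accentuation (Hanning midpoint)
  carrier <- make_pink_noise(10, seed = 7)
  acc <- apply_accentuation(carrier, 1000, 4000, accent_db = 12)
  p0 <- welch_psd(carrier, nfft = 16384)
  p1 <- welch_psd(acc, nfft = 16384)
  edge <- p0$freq_hz >= 990 & p0$freq_hz <= 1010
  gain_edge <- 10 * log10(sum(p1$psd[edge]) / sum(p0$psd[edge]))
  expect_equal(gain_edge, 6, tolerance = 0.5 / 6)

  # identity at zero gain
  acc0 <- apply_accentuation(carrier, 1000, 4000, accent_db = 0)
  expect_equal(acc0$samples, carrier$samples, tolerance = 1e-10)

  expect_error(apply_accentuation(carrier, 1000, 1050),
               class = "rippleRT_invalid_configuration")
})

# assembled trials ------------------------------------------------------------

test_that("assembled stimuli hit the canonical presentation levels", {
  bb <- fixture_bb_carrier()
  nb <- fixture_nb_carrier()
  lvl_bb <- measure_level_dbspl(bb, fixture_cal)
  lvl_nb <- measure_level_dbspl(nb, fixture_cal)
  expect_equal(lvl_bb, 74, tolerance = 0.5 / 74)
  expect_equal(lvl_nb, 68, tolerance = 0.5 / 68)
  # closed-form octave-power arithmetic: boosting k of N pink octaves by 15 dB
  n_oct <- log2(8700 / 100)
  gain_bb <- 10 * log10((n_oct - 5 + 5 * 10^1.5) / n_oct)
  gain_nb <- 10 * log10((n_oct - 1 + 1 * 10^1.5) / n_oct)
  expect_equal(lvl_bb, 60 + gain_bb, tolerance = 0.5 / 74)
  expect_equal(lvl_nb, 60 + gain_nb, tolerance = 0.5 / 68)
})

test_that("modulation onset is drawn uniformly from the 6-step grid", {
  grid <- seq(0.7, 1.2, by = 0.1)
  # the full trial path uses the grid...
  few <- vapply(1:24, function(s) {
    assemble_trial(ripple_spec("catch"), fixture_cal, seed = s,
                   mod_duration_s = 0.1, modulate = FALSE)$onset_s
  }, 0)
  expect_true(all(few %in% grid))
  # ...and 1000 seeded draws of the onset sampler are uniform over it
  onsets <- vapply(1:1000, rippleRT:::draw_onset_, 0)
  freq <- table(factor(onsets, levels = grid)) / 1000
  expect_true(all(abs(freq - 1 / 6) < 0.04))
})

test_that("identical spec, seed and calibration give bit-identical audio", {
  spec <- ripple_spec("broadband", omega = 1, rate_hz = 4)
  a <- assemble_trial(spec, fixture_cal, seed = 11)
  b <- assemble_trial(spec, fixture_cal, seed = 11)
  expect_identical(a$samples, b$samples)
  expect_identical(a$onset_s, b$onset_s)
})

test_that("accentuation and modulation gains commute in level", {
  carrier <- make_pink_noise(4, seed = 12)
  spec <- ripple_spec("broadband", omega = 0.5, rate_hz = 4)
  ab <- apply_stm(apply_accentuation(carrier, 250, 8000, 15), spec, 1)
  ba <- apply_accentuation(apply_stm(carrier, spec, 1), 250, 8000, 15)
  lvl <- function(x) 10 * log10(mean(x$samples^2))
  expect_lt(abs(lvl(ab) - lvl(ba)), 0.1)
})

test_that("the catch stimulus has no ripple-rate envelope peak", {
  spec_catch <- ripple_spec("catch")
  aud <- assemble_trial(spec_catch, fixture_cal, seed = 13, onset_s = 1,
                        mod_duration_s = 7)
  sr <- aud$sample_rate_hz
  env <- abs(aud$samples[(sr + 1):length(aud$samples)])
  env <- env - mean(env)
  n <- length(env)
  amp <- Mod(fft(env))[1:(n %/% 2)]
  freqs <- (0:(n %/% 2 - 1)) / (n / sr)
  floor_band <- freqs > 0.5 & freqs < 30
  noise_floor <- median(amp[floor_band])
  for (rate in c(4, 8, 16)) {
    at_rate <- amp[which.min(abs(freqs - rate))]
    expect_lt(at_rate, 6 * noise_floor)
  }
})

# level measurement and calibration -------------------------------------------

test_that("level measurement honors the calibration convention", {
  cal <- calibration_model(100)
  t <- seq(0, 1, length.out = 44100)
  sine <- trial_audio(sin(2 * pi * 1000 * t), 44100)
  expect_equal(measure_level_dbspl(sine, cal), 100, tolerance = 0.01 / 100)
  half <- trial_audio(0.5 * sin(2 * pi * 1000 * t), 44100)
  expect_equal(measure_level_dbspl(sine, cal) - measure_level_dbspl(half, cal),
               20 * log10(2), tolerance = 1e-3)
  # stationarity: disjoint windows of white noise agree
  wn <- trial_audio(withr::with_seed(1, rnorm(44100 * 10)) * 0.01, 44100)
  l1 <- measure_level_dbspl(wn, cal, window = c(0, 5))
  l2 <- measure_level_dbspl(wn, cal, window = c(5, 10))
  expect_lt(abs(l1 - l2), 0.2)
  expect_error(measure_level_dbspl(wn, cal, window = c(3, 3)),
               class = "rippleRT_invalid_argument")
})

# AGC stand-in -----------------------------------------------------------------

test_that("AGC stand-in reaches its steady-state reduction and stays stable", {
  aud <- fixture_bb_carrier(duration = 3, seed = 14)
  expect_identical(agc_standin(aud, gain_reduction_db = 0)$samples, aud$samples)
  comp <- agc_standin(aud, gain_reduction_db = 6)
  before <- measure_level_dbspl(aud, fixture_cal, window = c(0.6, 2.9))
  after <- measure_level_dbspl(comp, fixture_cal, window = c(0.6, 2.9))
  expect_equal(before - after, 6, tolerance = 0.5 / 6)
  # the compressor gain itself is flat across the onset-randomization window
  # (measured against the carrier, whose own short-window level fluctuates)
  gain <- vapply(seq(0.7, 1.1, by = 0.1), function(t0) {
    measure_level_dbspl(comp, fixture_cal, window = c(t0, t0 + 0.1)) -
      measure_level_dbspl(aud, fixture_cal, window = c(t0, t0 + 0.1))
  }, 0)
  expect_lt(max(gain) - min(gain), 0.5)
})

# WAV round trip ---------------------------------------------------------------

test_that("WAV write/read round-trips samples at 16-bit precision", {
  aud <- make_pink_noise(0.2, seed = 15)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(aud, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate_hz, 44100)
  expect_lt(max(abs(back$samples - aud$samples)), 1 / 32767)
})
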