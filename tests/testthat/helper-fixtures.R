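# shared fixtures built in code

# small calibrated unmodulated stimuli reused by several synthesis tests
fixture_cal <- calibration_model()

fixture_bb_carrier <- function(duration = 8, seed = 101) {
  assemble_trial(ripple_spec("catch"), fixture_cal, seed = seed,
                 onset_s = 1.0, mod_duration_s = duration - 1, modulate = FALSE)
}

fixture_nb_carrier <- function(duration = 8, seed = 102) {
  spec <- ripple_spec("narrowband", cf = 1000, omega = 0, rate_hz = 0)
  assemble_trial(spec, fixture_cal, seed = seed,
                 onset_s = 1.0, mod_duration_s = duration - 1, modulate = FALSE)
}

# censored LATER sample: rts coded at the ceiling, with flags
censored_later_sample <- function(params, n, seed, ceiling = 2.5) {
  rt <- simulate_later_rts(params, n, seed = seed)
  cens <- is.na(rt) | rt > ceiling
  rt[cens] <- ceiling
  list(rt = rt, censored = cens)
}

# minimal clean trial tibble for pipeline tests
make_clean_tbl <- function(rt, censored = rep(FALSE, length(rt)),
                           participant = "S01", implementation = "Laptop",
                           stimulus_id = "bb_4Hz_0.5co", block = 1) {
  tibble::tibble(participant = participant, implementation = implementation,
                 stimulus_id = stimulus_id, block = block,
                 rt_s = rt, censored = censored)
}
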