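#' LATER-model response parameters for one listener-stimulus pair
#'
#' Under the LATER model a decision signal rises linearly at a rate drawn per
#' trial from a Gaussian; reaction time is the reciprocal of that rate, so
#' *promptness* (1/RT) is normally distributed. The model is parameterized
#' directly on the promptness scale because threshold and rise rate are not
#' separately identifiable from reaction times alone.
#'
#' @param mu_p median promptness in 1/s (mean of the Gaussian promptness
#'   distribution); must be positive.
#' @param sigma_p promptness SD in 1/s; positive.
#' @param lapse_rate probability of a non-response (stimulus never detected).
#' @param fp_rate_hz rate (1/s) of stimulus-independent false-positive
#'   responses, modeled as a homogeneous Poisson process from noise onset
#'   racing the stimulus-driven response.
#' @return an object of class `later_params`.
#' @export
later_params <- function(mu_p, sigma_p, lapse_rate = 0, fp_rate_hz = 0) {
  assert_scalar_num_(mu_p, "mu_p", lower = 1e-12)
  assert_scalar_num_(sigma_p, "sigma_p", lower = 0)
  assert_scalar_num_(lapse_rate, "lapse_rate", lower = 0, upper = 1)
  assert_scalar_num_(fp_rate_hz, "fp_rate_hz", lower = 0)
  structure(list(mu_p = mu_p, sigma_p = sigma_p, lapse_rate = lapse_rate,
                 fp_rate_hz = fp_rate_hz), class = "later_params")
}

#' Draw LATER reaction times
#'
#' Draws promptness `p ~ Normal(mu_p, sigma_p)` truncated to `p > 0` and
#' returns `RT = 1/p`; with probability `lapse_rate` a trial is a non-response
#' (`NA`).
#'
#' @param params a [later_params()].
#' @param n number of trials.
#' @param seed integer seed for reproducibility.
#' @return numeric vector of reaction times in seconds, `NA` for lapses.
#' @export
simulate_later_rts <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "later_params"), n >= 1)
  with_seed_(seed, {
    p <- rnorm(n, params$mu_p, params$sigma_p)
    while (any(p <= 0)) {
      p[p <= 0] <- rnorm(sum(p <= 0), params$mu_p, params$sigma_p)
    }
    rt <- 1 / p
    rt[runif(n) < params$lapse_rate] <- NA_real_
    rt
  })
}

#' Cohort configuration for the trial simulator
#'
#' Defines the study conditions for a synthetic cohort of LATER listeners:
#' per-stimulus baseline promptness, how a latent spectrotemporal-sensitivity
#' trait loads on each stimulus, between-listener variability, response
#' contaminants and the recording delay of the App implementation.
#'
#' Baseline median reaction times reflect the canonical difficulty ordering of
#' the stimulus set: fast responses to temporally modulated broadband ripples,
#' slow responses to purely spectral high-density ripples and to low-frequency
#' narrowband ripples. Trait loadings are positive (on log-promptness) for the
#' speech-relevant conditions (densities 0.25--1 c/o at rates up to 16 Hz and
#' the 4 kHz narrowband ripple) and zero for the purely temporal 8 Hz ripple,
#' the 2 c/o ripples and the remaining narrowband conditions.
#'
#' @param n_participants cohort size (default 20).
#' @param implementation_delay_s fixed technical delay added to App-recorded
#'   reaction times (default 0.470 s).
#' @param trait_loading log-promptness gain per trait SD on speech-relevant
#'   stimuli (default 0.4).
#' @param participant_sd SD of a general log-promptness speed offset per
#'   listener (default 0.2).
#' @param interaction_sd SD of idiosyncratic listener-by-stimulus
#'   log-promptness noise (default 0.1).
#' @param sigma_p_cv promptness SD as a fraction of `mu_p` (default 0.25).
#' @param lapse_rate,fp_rate_hz response contaminants (defaults 0.03, 0.02).
#' @param b_trait,b_age,srt_noise_sd coefficients of the linear link from the
#'   trait and z-scored age to the true speech-reception threshold, in dB
#'   (defaults -2, 1, 1): more sensitive listeners have lower (better) SRTs.
#' @param n_blocks,n_trials_per_stimulus protocol counts (2 blocks of 10
#'   trials per stimulus and implementation).
#' @param response_window_s response window after modulation onset (3 s).
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 20,
                          implementation_delay_s = 0.470,
                          trait_loading = 0.4,
                          participant_sd = 0.2,
                          interaction_sd = 0.1,
                          sigma_p_cv = 0.25,
                          lapse_rate = 0.03,
                          fp_rate_hz = 0.02,
                          b_trait = -2, b_age = 1, srt_noise_sd = 1,
                          n_blocks = 2, n_trials_per_stimulus = 10,
                          response_window_s = 3) {
  base <- baseline_difficulty_()
  structure(
    list(n_participants = n_participants,
         implementation_delay_s = implementation_delay_s,
         trait_loading = trait_loading,
         participant_sd = participant_sd,
         interaction_sd = interaction_sd,
         sigma_p_cv = sigma_p_cv,
         lapse_rate = lapse_rate,
         fp_rate_hz = fp_rate_hz,
         b_trait = b_trait, b_age = b_age, srt_noise_sd = srt_noise_sd,
         n_blocks = n_blocks,
         n_trials_per_stimulus = n_trials_per_stimulus,
         response_window_s = response_window_s,
         baseline = base),
    class = "cohort_config")
}

# canonical per-stimulus baseline median RT (s) and trait loading (fraction of
# `trait_loading` applied on log-promptness); speech-relevant conditions load,
# the purely temporal 8 Hz, the 2 c/o and the low-CF narrowband ones do not
baseline_difficulty_ <- function() {
  tibble::tribble(
    ~stimulus_id,      ~median_rt_s, ~loads_on_trait,
    "nb_500Hz",        1.75,         FALSE,
    "nb_1000Hz",       1.30,         FALSE,
    "nb_2000Hz",       0.95,         FALSE,
    "nb_4000Hz",       1.00,         TRUE,
    "bb_0Hz_2co",      2.00,         FALSE,
    "bb_0Hz_1co",      1.30,         TRUE,
    "bb_0Hz_0.5co",    0.90,         TRUE,
    "bb_0Hz_0.25co",   0.55,         TRUE,
    "bb_4Hz_2co",      0.90,         FALSE,
    "bb_4Hz_1co",      0.65,         TRUE,
    "bb_4Hz_0.5co",    0.50,         TRUE,
    "bb_4Hz_0co",      0.55,         FALSE,
    "bb_8Hz_1co",      0.55,         TRUE,
    "bb_8Hz_0.5co",    0.50,         TRUE,
    "bb_8Hz_0co",      0.50,         FALSE,
    "bb_16Hz_0.25co",  0.50,         TRUE,
    "bb_catch",        NA_real_,     FALSE
  )
}

#' Link a latent sensitivity trait to a speech-reception threshold
#'
#' Ground-truth linear link used by the cohort simulator:
#' `srt_true_db = b_trait * trait + b_age * z(age) + Normal(0, noise_sd)`.
#' With `b_trait < 0`, more sensitive listeners get lower (better) thresholds.
#'
#' @param trait latent trait values (z-scored scale).
#' @param age_z z-scored ages (same length, or scalar 0).
#' @param b_trait,b_age,noise_sd link coefficients (dB per SD) and residual SD.
#' @param seed integer seed.
#' @return numeric vector of true 50% speech-reception thresholds in dB SNR.
#' @export
link_srt <- function(trait, age_z = 0, b_trait = -2, b_age = 1, noise_sd = 1,
                     seed = NULL) {
  stopifnot(all(is.finite(c(b_trait, b_age, noise_sd))))
  eps <- if (noise_sd > 0) with_seed_(seed, rnorm(length(trait), 0, noise_sd)) else 0
  b_trait * trait + b_age * age_z + eps
}

#' Simulate a synthetic cohort and its trial-by-trial reaction times
#'
#' Generates listener profiles (latent trait, age, per-stimulus LATER
#' parameters, true speech-reception threshold) and then simulates every trial
#' of the protocol: for each listener, implementation and block, the trials
#' per stimulus in pseudorandom order. Stimulus-driven LATER responses race a
#' homogeneous Poisson false-positive process running from noise onset; the
#' earliest event within the response window wins. Responses falling before
#' modulation onset are regenerated (the trial is reiterated) and counted.
#' App-recorded reaction times include the configured technical delay. Catch
#' trials carry no stimulus-driven response and can only yield false positives
#' or non-responses.
#'
#' @param config a [cohort_config()].
#' @param seed root integer seed; every listener gets an independent stream.
#' @return a list with `profiles` (one row per listener: `participant`,
#'   `age_years`, `trait`, `srt_true_db`, `implementation_delay_s`),
#'   `later_params` (one row per listener-stimulus: `mu_p`, `sigma_p`,
#'   `lapse_rate`, `fp_rate_hz`), and `trials` (one row per trial:
#'   `participant`, `implementation`, `stimulus_id`, `block`, `trial`,
#'   `onset_s`, `rt_raw_s`, `responded`, `premature_reiterations`).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  seeds <- spawn_seeds_(seed, n + 1L)
  profiles <- with_seed_(seeds[n + 1L], {
    trait <- rnorm(n)
    age <- runif(n, 40, 80)
    age_z <- as.numeric(scale(age))
    tibble::tibble(
      participant = sprintf("S%02d", seq_len(n)),
      age_years = age,
      trait = trait,
      srt_true_db = link_srt(trait, age_z, config$b_trait, config$b_age,
                             config$srt_noise_sd),
      implementation_delay_s = config$implementation_delay_s
    )
  })
  base <- config$baseline
  per_listener <- purrr::map(seq_len(n), function(i) {
    with_seed_(seeds[i], {
      gamma <- rnorm(1, 0, config$participant_sd)
      eps <- rnorm(nrow(base), 0, config$interaction_sd)
      loading <- ifelse(base$loads_on_trait, config$trait_loading, 0)
      mu_p <- (1 / base$median_rt_s) *
        exp(loading * profiles$trait[i] + gamma + eps)
      lp <- tibble::tibble(
        participant = profiles$participant[i],
        stimulus_id = base$stimulus_id,
        mu_p = mu_p,
        sigma_p = config$sigma_p_cv * mu_p,
        lapse_rate = ifelse(is.na(mu_p), NA_real_, config$lapse_rate),
        fp_rate_hz = config$fp_rate_hz
      )
      trials <- simulate_listener_trials_(lp, config)
      list(later = lp, trials = trials)
    })
  })
  list(profiles = profiles,
       later_params = dplyr::bind_rows(purrr::map(per_listener, "later")),
       trials = dplyr::bind_rows(purrr::map(per_listener, "trials")))
}

# all trials for one listener; runs inside that listener's seeded stream
simulate_listener_trials_ <- function(lp, config) {
  onset_grid <- seq(0.7, 1.2, by = 0.1)
  n_rep <- config$n_trials_per_stimulus
  win <- config$response_window_s
  grid <- tidyr::expand_grid(
    implementation = c("App", "Laptop"),
    block = seq_len(config$n_blocks),
    stimulus_id = lp$stimulus_id,
    trial = seq_len(n_rep)
  )
  # pseudorandom presentation order within each implementation x block
  grid <- grid |>
    dplyr::group_by(.data$implementation, .data$block) |>
    dplyr::slice_sample(prop = 1) |>
    dplyr::mutate(presentation = dplyr::row_number()) |>
    dplyr::ungroup()
  m <- nrow(grid)
  idx <- match(grid$stimulus_id, lp$stimulus_id)
  mu <- lp$mu_p[idx]; sig <- lp$sigma_p[idx]
  lapse <- lp$lapse_rate[idx]; fp <- lp$fp_rate_hz[idx]
  onset <- sample(onset_grid, m, replace = TRUE)
  draw_for <- function(j) {
    k <- length(j)
    # stimulus-driven LATER response (Inf when lapsed or catch, where mu is NA)
    mu_j <- ifelse(is.na(mu[j]), 1, mu[j])
    sig_j <- ifelse(is.na(sig[j]), 1, sig[j])
    p <- rnorm(k, mu_j, sig_j)
    while (any(p <= 0)) {
      p[p <= 0] <- rnorm(sum(p <= 0), mu_j[p <= 0], sig_j[p <= 0])
    }
    t_later <- ifelse(is.na(mu[j]) | runif(k) < lapse[j], Inf, 1 / p)
    # first false positive from noise onset, relative to modulation onset
    t_fp <- ifelse(fp[j] > 0, rexp(k, pmax(fp[j], 1e-12)) - onset[j], Inf)
    list(later = t_later, fp = t_fp)
  }
  d <- draw_for(seq_len(m))
  premature <- integer(m)
  # a false positive before modulation onset reiterates the whole trial
  repeat {
    pre <- which(d$fp < 0)
    if (!length(pre)) break
    premature[pre] <- premature[pre] + 1L
    redraw <- draw_for(pre)
    d$later[pre] <- redraw$later
    d$fp[pre] <- redraw$fp
  }
  rt <- pmin(d$later, d$fp)
  responded <- rt <= win
  rt[!responded] <- NA_real_
  rt_rec <- ifelse(grid$implementation == "App",
                   rt + config$implementation_delay_s, rt)
  tibble::tibble(
    participant = lp$participant[1],
    implementation = grid$implementation,
    stimulus_id = grid$stimulus_id,
    block = grid$block,
    trial = grid$trial,
    onset_s = onset,
    rt_raw_s = rt_rec,
    responded = responded,
    premature_reiterations = premature
  )
}
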