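#' Psychometric listener for the matrix speech-in-noise test
#'
#' Word-correct probability of a matrix-test listener as a function of SNR:
#' `P(snr) = guess + (1 - guess - lapse) * plogis((snr - srt50_db)/s)`,
#' where `srt50_db` is the *midpoint* of the guess/lapse-corrected logistic
#' (so `P(srt50_db) = guess + (1 - guess - lapse)/2`, e.g. 0.55 with the
#' default 1/10 guessing floor and no lapses) and `s` is set so the slope of
#' `P` at the midpoint equals `slope` (probability per dB). The guessing floor
#' of 1/10 reflects forced selection of one word per 10-word column.
#'
#' @param srt50_db threshold (psychometric midpoint) in dB SNR.
#' @param slope slope of `P` at threshold, probability/dB (default 0.15).
#' @param guess guessing floor (default 0.1).
#' @param lapse ceiling deficit (default 0).
#' @return an object of class `matrix_listener`.
#' @export
matrix_listener <- function(srt50_db, slope = 0.15, guess = 0.1, lapse = 0) {
  assert_scalar_num_(srt50_db, "srt50_db")
  assert_scalar_num_(slope, "slope", lower = 1e-6)
  assert_scalar_num_(guess, "guess", lower = 0, upper = 1)
  assert_scalar_num_(lapse, "lapse", lower = 0, upper = 1 - guess)
  structure(list(srt50_db = srt50_db, slope = slope, guess = guess,
                 lapse = lapse,
                 s = (1 - guess - lapse) / (4 * slope)),
            class = "matrix_listener")
}

#' @rdname matrix_listener
#' @param listener a `matrix_listener`.
#' @param snr_db SNR(s) in dB.
#' @return `word_prob()`: word-correct probability at `snr_db`.
#' @export
word_prob <- function(listener, snr_db) {
  with(listener,
       guess + (1 - guess - lapse) * plogis((snr_db - srt50_db) / s))
}

#' Simulate one matrix sentence
#'
#' Five independent Bernoulli word draws at the listener's word-correct
#' probability for the presented SNR.
#'
#' @param listener a [matrix_listener()].
#' @param snr_db presentation SNR in dB.
#' @param seed integer seed.
#' @return integer count of correct words (0--5).
#' @export
respond_sentence <- function(listener, snr_db, seed = NULL) {
  p <- word_prob(listener, snr_db)
  with_seed_(seed, rbinom(1, 5, p))
}

# ML fit of the logistic midpoint and spread to (snr, k of 5) data with a
# fixed guessing floor; returns NULL when not identifiable
fit_psychometric_ <- function(snr, k, guess = 0.1, lapse = 0) {
  if (length(unique(snr)) < 2 || all(k == 5) || all(k == 0)) return(NULL)
  nll <- function(par) {
    mid <- par[1]; s <- exp(par[2])
    p <- guess + (1 - guess - lapse) * plogis((snr - mid) / s)
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(k * log(p) + (5 - k) * log(1 - p))
  }
  opt <- tryCatch(
    optim(c(mean(snr), log(1.5)), nll, method = "L-BFGS-B",
          lower = c(-40, log(0.2)), upper = c(40, log(12))),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) return(NULL)
  # binomial deviance against the saturated model
  phat <- pmin(pmax(k / 5, 1e-9), 1 - 1e-9)
  ll_sat <- sum(k * log(phat) + (5 - k) * log(1 - phat))
  list(mid = opt$par[1], s = exp(opt$par[2]),
       deviance = 2 * (ll_sat + opt$value), df = length(snr) - 2)
}

#' Run one adaptive matrix-test track
#'
#' Adaptive 20-sentence speech-in-noise track targeting the 50% threshold.
#' The first sentence is presented at +10 dB SNR. Until the maximum-likelihood
#' psychometric fit is identifiable (both fully correct and partly incorrect
#' sentences observed), the SNR descends 2 dB after a sentence with at least
#' three correct words and rises 2 dB otherwise. Once identifiable, a logistic
#' psychometric function (fixed guessing floor) is refit by maximum likelihood
#' to all data so far and the next sentence is placed at the current threshold
#' estimate. The final threshold is the midpoint of the 20-sentence fit; if
#' the fit fails or its deviance exceeds `fallback_deviance_ratio` times its
#' degrees of freedom, the mean of the final 8 presented SNRs is used instead
#' and `fallback_used` is set.
#'
#' @param listener a [matrix_listener()].
#' @param n_sentences track length (default 20).
#' @param start_snr_db first presentation SNR (default +10 dB).
#' @param step_db descent/ascent step before the fit is identifiable (2 dB).
#' @param fallback_deviance_ratio fit-error criterion (default 1.5).
#' @param seed integer seed.
#' @return an object of class `adaptive_run`: `snr_track`, `words_correct`,
#'   `srt_est_db`, `fit_ok`, `fallback_used`.
#' @export
run_adaptive <- function(listener, n_sentences = 20, start_snr_db = 10,
                         step_db = 2, fallback_deviance_ratio = 1.5,
                         seed = NULL) {
  stopifnot(inherits(listener, "matrix_listener"))
  with_seed_(seed, {
    snr <- numeric(n_sentences)
    k <- integer(n_sentences)
    snr[1] <- start_snr_db
    for (i in seq_len(n_sentences)) {
      k[i] <- rbinom(1, 5, word_prob(listener, snr[i]))
      if (i == n_sentences) break
      fit <- fit_psychometric_(snr[seq_len(i)], k[seq_len(i)],
                               guess = listener$guess)
      snr[i + 1] <- if (!is.null(fit)) {
        fit$mid
      } else if (k[i] >= 3) {
        snr[i] - step_db
      } else {
        snr[i] + step_db
      }
    }
    fit <- fit_psychometric_(snr, k, guess = listener$guess)
    fit_ok <- !is.null(fit) &&
      fit$deviance <= fallback_deviance_ratio * fit$df
    fallback <- !fit_ok
    srt_est <- if (fallback || is.null(fit)) {
      mean(tail(snr, 8))
    } else {
      fit$mid
    }
    structure(list(snr_track = snr, words_correct = k,
                   srt_est_db = srt_est, fit_ok = fit_ok,
                   fallback_used = fallback),
              class = "adaptive_run")
  })
}

#' @export
print.adaptive_run <- function(x, ...) {
  cat(sprintf("<adaptive_run> SRT %.2f dB SNR over %d sentences%s\n",
              x$srt_est_db, length(x$snr_track),
              if (x$fallback_used) " [fallback: mean of last 8 SNRs]" else ""))
  invisible(x)
}

#' Simulate speech-reception thresholds for a cohort
#'
#' Runs `n_lists` adaptive tracks per listener against a psychometric
#' listener centered on the profile's true threshold, and reports their mean
#' (the protocol uses the mean of two tests).
#'
#' @param profiles tibble with `participant` and `srt_true_db` (from
#'   [simulate_cohort()]).
#' @param n_lists adaptive tracks per listener (default 2).
#' @param slope psychometric slope passed to [matrix_listener()].
#' @param seed root integer seed.
#' @return tibble with `participant`, `srt_db` (mean estimate),
#'   `srt_true_db`, `n_fallback`.
#' @export
simulate_srt <- function(profiles, n_lists = 2, slope = 0.15, seed = 1) {
  stopifnot(all(c("participant", "srt_true_db") %in% names(profiles)))
  seeds <- spawn_seeds_(seed, nrow(profiles) * n_lists)
  purrr::map(seq_len(nrow(profiles)), function(i) {
    listener <- matrix_listener(profiles$srt_true_db[i], slope = slope)
    runs <- purrr::map(seq_len(n_lists), function(j) {
      run_adaptive(listener, seed = seeds[(i - 1) * n_lists + j])
    })
    tibble::tibble(
      participant = profiles$participant[i],
      srt_db = mean(purrr::map_dbl(runs, "srt_est_db")),
      srt_true_db = profiles$srt_true_db[i],
      n_fallback = sum(purrr::map_lgl(runs, "fallback_used"))
    )
  }) |>
    dplyr::bind_rows()
}
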