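# Bias-corrected and accelerated (BCa) interval from a bootstrap distribution:
# z0 from the proportion of bootstrap statistics below the point estimate,
# acceleration from the skewness of jackknife influence values.
bca_interval_ <- function(boot_stats, theta_hat, jack_stats, conf = 0.95) {
  alpha <- (1 - conf) / 2
  prop <- mean(boot_stats < theta_hat)
  if (prop <= 0 || prop >= 1 || sd(boot_stats) == 0) {
    # degenerate bootstrap distribution
    return(c(theta_hat, theta_hat))
  }
  z0 <- qnorm(prop)
  jm <- mean(jack_stats)
  num <- sum((jm - jack_stats)^3)
  den <- 6 * sum((jm - jack_stats)^2)^1.5
  a <- if (den == 0) 0 else num / den
  zq <- qnorm(c(alpha, 1 - alpha))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  unname(quantile(boot_stats, adj, type = 7))
}

#' Bootstrapped difference of means with a BCa interval
#'
#' Effect size (difference of means, `mean(x) - mean(y)`) with a 95%
#' bias-corrected and accelerated (BCa) bootstrap interval and a two-sided
#' bootstrap p-value. Resampling is unpaired and with replacement; the BCa
#' bounds correct the percentile interval for bias (`z0`, from the proportion
#' of bootstrap statistics below the estimate) and skewness (acceleration `a`,
#' from the jackknife influence values of both samples). The p-value is the
#' doubled tail probability of zero under the bootstrap distribution, floored
#' at `2/n_boot`.
#'
#' @param x,y numeric samples (at least 2 values each).
#' @param n_boot bootstrap resamples (default 5000).
#' @param conf interval coverage (default 0.95).
#' @param seed integer seed.
#' @return an object of class `effect_size`: `delta`, `ci_lo`, `ci_hi`,
#'   `p_boot`, `n_boot`, `n_x`, `n_y`.
#' @export
bootstrap_mean_diff <- function(x, y, n_boot = 5000, conf = 0.95, seed = NULL) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  delta <- mean(x) - mean(y)
  if (sd(x) == 0 && sd(y) == 0) {
    warn("constant samples: degenerate bootstrap interval")
    return(structure(list(delta = delta, ci_lo = delta, ci_hi = delta,
                          p_boot = if (delta == 0) 1 else 2 / n_boot,
                          n_boot = n_boot, n_x = length(x), n_y = length(y)),
                     class = "effect_size"))
  }
  boots <- with_seed_(seed, {
    bx <- colMeans(matrix(sample(x, length(x) * n_boot, replace = TRUE),
                          nrow = length(x)))
    by <- colMeans(matrix(sample(y, length(y) * n_boot, replace = TRUE),
                          nrow = length(y)))
    bx - by
  })
  # jackknife influence of every observation on the difference of means
  jack <- c((sum(x) - x) / (length(x) - 1) - mean(y),
            mean(x) - (sum(y) - y) / (length(y) - 1))
  ci <- bca_interval_(boots, delta, jack, conf)
  p <- max(2 * min(mean(boots <= 0), mean(boots >= 0)), 2 / n_boot)
  structure(list(delta = delta, ci_lo = ci[1], ci_hi = ci[2],
                 p_boot = min(p, 1), n_boot = n_boot,
                 n_x = length(x), n_y = length(y)),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> delta %.4g [%.4g, %.4g] (BCa 95%%), p_boot %.4g (n_boot %d)\n",
              x$delta, x$ci_lo, x$ci_hi, x$p_boot, x$n_boot))
  invisible(x)
}

#' @rdname bootstrap_mean_diff
#' @param x an `effect_size` object (for the `tidy` method).
#' @param ... unused.
#' @export
tidy.effect_size <- function(x, ...) {
  tibble::tibble(delta = x$delta, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
                 p_boot = x$p_boot, n_boot = x$n_boot)
}

#' Compare implementations per stimulus using all individual trials
#'
#' For each stimulus, bootstraps the difference in mean reaction time (or
#' promptness) between two implementations, pooling all individual retained
#' trials across participants rather than per-participant medians.
#'
#' @param clean preprocessed trials from [preprocess_rt()].
#' @param scale `"rt"` (seconds) or `"promptness"` (1/s).
#' @param implementations length-2 character: difference is first minus second.
#' @param include_censored include censored codes in the means (default TRUE).
#' @param n_boot,seed passed to [bootstrap_mean_diff()].
#' @return tibble with one [tidy.effect_size()] row per stimulus.
#' @export
compare_implementations <- function(clean, scale = c("rt", "promptness"),
                                    implementations = c("App", "Laptop"),
                                    include_censored = TRUE,
                                    n_boot = 5000, seed = NULL) {
  scale <- match.arg(scale)
  stopifnot(all(c("implementation", "stimulus_id", "rt_s") %in% names(clean)))
  if (!include_censored) clean <- dplyr::filter(clean, !.data$censored)
  val <- if (scale == "rt") clean$rt_s else 1 / clean$rt_s
  clean$value_ <- val
  ids <- unique(clean$stimulus_id)
  seeds <- spawn_seeds_(seed %||% sample.int(1e7, 1), length(ids))
  purrr::map2(ids, seeds, function(id, s) {
    d <- clean[clean$stimulus_id == id, ]
    x <- d$value_[d$implementation == implementations[1]]
    y <- d$value_[d$implementation == implementations[2]]
    dplyr::bind_cols(tibble::tibble(stimulus_id = id),
                     tidy(bootstrap_mean_diff(x, y, n_boot = n_boot, seed = s)))
  }) |>
    dplyr::bind_rows()
}

#' Modulation transfer functions from reaction times
#'
#' Per-stimulus mean reaction time (or promptness) over all retained trials
#' across participants, with bootstrap 95% confidence bounds, joined to the
#' stimulus grid so the table slices directly into iso-velocity rows (spectral
#' MTF: RT against density at fixed rate), iso-density rows (temporal MTF),
#' and the narrowband row over center frequency.
#'
#' @param clean preprocessed trials from [preprocess_rt()].
#' @param scale `"rt"` or `"promptness"`.
#' @param include_censored include censored codes in the means (default TRUE,
#'   so non-detections slow the mean as they do in the protocol).
#' @param n_boot bootstrap resamples for the interval (default 2000).
#' @param seed integer seed.
#' @return a tibble of class `mtf_table`: `stimulus_id`, grid columns
#'   (`band_kind`, `rate_hz`, `omega`, `cf_hz`), `mean_value`, `ci_lo`,
#'   `ci_hi`, `mean_rt_s`, `mean_promptness`, `n`.
#' @export
mtf <- function(clean, scale = c("rt", "promptness"), include_censored = TRUE,
                n_boot = 2000, seed = NULL) {
  scale <- match.arg(scale)
  stopifnot(all(c("stimulus_id", "rt_s") %in% names(clean)))
  if (!include_censored) clean <- dplyr::filter(clean, !.data$censored)
  clean$value_ <- if (scale == "rt") clean$rt_s else 1 / clean$rt_s
  ids <- unique(clean$stimulus_id)
  seeds <- spawn_seeds_(seed %||% sample.int(1e7, 1), length(ids))
  rows <- purrr::map2(ids, seeds, function(id, s) {
    v <- clean$value_[clean$stimulus_id == id]
    ci <- if (length(v) >= 2 && sd(v) > 0) {
      boots <- with_seed_(s, colMeans(matrix(sample(v, length(v) * n_boot,
                                                    replace = TRUE),
                                             nrow = length(v))))
      jack <- (sum(v) - v) / (length(v) - 1)
      bca_interval_(boots, mean(v), jack)
    } else c(mean(v), mean(v))
    tibble::tibble(stimulus_id = id, mean_value = mean(v),
                   ci_lo = ci[1], ci_hi = ci[2],
                   mean_rt_s = mean(clean$rt_s[clean$stimulus_id == id]),
                   mean_promptness = mean(1 / clean$rt_s[clean$stimulus_id == id]),
                   n = length(v))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::left_join(
      dplyr::select(stimulus_table(), "stimulus_id", "band_kind",
                    "rate_hz", "omega", "cf_hz"),
      by = "stimulus_id") |>
    dplyr::relocate("band_kind", "rate_hz", "omega", "cf_hz",
                    .after = "stimulus_id")
  class(out) <- c("mtf_table", class(out))
  attr(out, "scale") <- scale
  out
}
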