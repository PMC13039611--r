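#' Reciprobit points for one reaction-time set
#'
#' Builds the points of a reciprobit plot: uncensored reaction times are
#' sorted and given Hazen plotting positions `(i - 0.5) / n`, where `n` counts
#' *all* trials including censored ones, so misses depress the reachable
#' asymptote. Each point pairs promptness (`1/RT`) with the probit of its
#' cumulative probability; censored trials contribute no point. On the plot
#' the promptness axis is drawn reversed (fast responses on the left).
#'
#' @param rt_s reaction times in seconds (censored values included), or a data
#'   frame holding `rt_s` and `censored`.
#' @param censored logical vector marking censored trials.
#' @return tibble with `rt_s`, `promptness`, `cum_prob`, `probit`.
#' @export
reciprobit_points <- function(rt_s, censored = NULL) {
  if (is.data.frame(rt_s)) {
    censored <- rt_s$censored
    rt_s <- rt_s$rt_s
  }
  censored <- censored %||% rep(FALSE, length(rt_s))
  stopifnot(length(censored) == length(rt_s))
  n <- length(rt_s)
  obs <- sort(rt_s[!censored])
  if (length(obs) < 2) {
    abort("need at least 2 uncensored responses for a reciprobit plot",
          class = "rippleRT_insufficient_data")
  }
  cum <- (seq_along(obs) - 0.5) / n
  tibble::tibble(rt_s = obs, promptness = 1 / obs,
                 cum_prob = cum, probit = qnorm(cum))
}

#' Fit the LATER model to a censored reaction-time set
#'
#' Estimates the promptness mean and SD of a LATER (reciprocal-normal)
#' reaction-time distribution. `"mle_censored"` (default) maximizes the
#' likelihood of promptness `~ Normal(mu_p, sigma_p)` in which right-censored
#' reaction times (at the ceiling) enter through the normal CDF below the
#' censoring promptness `1/ceiling`. `"ls_line"` fits a least-squares line to
#' the reciprobit points and back-solves `(mu_p, sigma_p)`; it ignores the
#' information in the censored mass beyond the plotting positions and is kept
#' for parity with classic LATER practice.
#'
#' @param rt_s reaction times (censored values coded at the ceiling), or a
#'   data frame holding `rt_s` and `censored`.
#' @param censored logical censoring flags.
#' @param method `"mle_censored"` or `"ls_line"`.
#' @param ceiling_s censoring ceiling in seconds (default 2.5).
#' @return an object of class `later_fit` with elements `mu_p_hat`,
#'   `sigma_p_hat`, `n_used`, `n_censored`, `r2_line`, `method`, `converged`.
#' @export
fit_later <- function(rt_s, censored = NULL,
                      method = c("mle_censored", "ls_line"), ceiling_s = 2.5) {
  method <- match.arg(method)
  if (is.data.frame(rt_s)) {
    censored <- rt_s$censored
    rt_s <- rt_s$rt_s
  }
  censored <- censored %||% rep(FALSE, length(rt_s))
  obs_p <- 1 / rt_s[!censored]
  n_cens <- sum(censored)
  n_obs <- length(obs_p)
  if (method == "mle_censored" && n_obs < 5) {
    abort("mle_censored needs at least 5 uncensored responses",
          class = "rippleRT_insufficient_data")
  }
  pts <- reciprobit_points(rt_s, censored)
  line <- lm(probit ~ promptness, data = pts)
  r2 <- summary(line)$r.squared
  if (method == "ls_line") {
    # under the model probit = (mu_p - promptness) / sigma_p, so the fitted
    # line has slope -1/sigma_p and intercept mu_p/sigma_p
    b <- coef(line)
    sigma_hat <- -1 / b[["promptness"]]
    mu_hat <- b[["(Intercept)"]] * sigma_hat
    converged <- is.finite(mu_hat) && sigma_hat > 0
  } else {
    p_cens <- 1 / ceiling_s
    nll <- function(par) {
      mu <- exp(par[1]); sig <- exp(par[2])
      # promptness is normal truncated to p > 0 (reaction times are positive);
      # censored trials contribute the mass between 0 and the ceiling
      # promptness, both renormalized by the truncation constant
      log_z <- pnorm(mu / sig, log.p = TRUE)
      ll <- sum(dnorm(obs_p, mu, sig, log = TRUE)) - n_obs * log_z
      if (n_cens > 0) {
        mass <- pnorm(p_cens, mu, sig) - pnorm(0, mu, sig)
        ll <- ll + n_cens * (log(max(mass, 1e-300)) - log_z)
      }
      -ll
    }
    init <- c(log(mean(obs_p)), log(max(sd(obs_p), 1e-3)))
    opt <- tryCatch(optim(init, nll, method = "BFGS"),
                    error = function(e) NULL)
    if (is.null(opt) || opt$convergence != 0) {
      # fall back to a derivative-free restart before flagging
      opt2 <- tryCatch(optim(init, nll), error = function(e) NULL)
      if (!is.null(opt2)) opt <- opt2
    }
    converged <- !is.null(opt) && opt$convergence == 0
    if (is.null(opt)) {
      mu_hat <- mean(obs_p); sigma_hat <- sd(obs_p)
    } else {
      mu_hat <- exp(opt$par[1]); sigma_hat <- exp(opt$par[2])
    }
  }
  structure(list(mu_p_hat = unname(mu_hat), sigma_p_hat = unname(sigma_hat),
                 n_used = n_obs + n_cens, n_censored = n_cens,
                 r2_line = r2, method = method, ceiling_s = ceiling_s,
                 converged = converged, points = pts),
            class = "later_fit")
}

#' @export
print.later_fit <- function(x, ...) {
  cat(sprintf("<later_fit:%s> mu_p %.3f 1/s, sigma_p %.3f 1/s (n %d, censored %d, line R2 %.3f)%s\n",
              x$method, x$mu_p_hat, x$sigma_p_hat, x$n_used, x$n_censored,
              x$r2_line, if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @rdname fit_later
#' @param x a `later_fit` object.
#' @param ... unused.
#' @export
tidy.later_fit <- function(x, ...) {
  tibble::tibble(term = c("mu_p", "sigma_p"),
                 estimate = c(x$mu_p_hat, x$sigma_p_hat))
}

#' @rdname fit_later
#' @export
glance.later_fit <- function(x, ...) {
  tibble::tibble(mu_p_hat = x$mu_p_hat, sigma_p_hat = x$sigma_p_hat,
                 n_used = x$n_used, n_censored = x$n_censored,
                 r2_line = x$r2_line, method = x$method,
                 converged = x$converged)
}

#' Fit the LATER model per stimulus cell
#'
#' Applies [fit_later()] within each (participant, implementation, stimulus)
#' cell of a preprocessed trial table.
#'
#' @param clean preprocessed trials from [preprocess_rt()].
#' @param method,ceiling_s passed to [fit_later()].
#' @param min_uncensored cells with fewer uncensored responses are skipped.
#' @return tibble of per-cell [glance.later_fit()] rows.
#' @export
fit_later_by_cell <- function(clean, method = "mle_censored", ceiling_s = 2.5,
                              min_uncensored = 5) {
  key <- intersect(c("participant", "implementation", "stimulus_id"), names(clean))
  clean |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::group_modify(function(d, g) {
      if (sum(!d$censored) < min_uncensored) return(tibble::tibble())
      glance(fit_later(d$rt_s, d$censored, method = method,
                       ceiling_s = ceiling_s))
    }) |>
    dplyr::ungroup()
}
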