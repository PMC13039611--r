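#' Spearman correlations between ripple reaction times and speech thresholds
#'
#' Per stimulus, correlates participants' pooled median reaction times with
#' their speech-reception thresholds using Spearman's rank coefficient
#' (midranks for ties), applies step-down Holm correction over the stated
#' family size, and adds the Pearson correlation on promptness with a
#' Bayesian 95% credible interval (see [bayes_pearson_ci()]).
#'
#' @param medians output of [pool_median()] (one implementation, or filter
#'   beforehand); needs `participant`, `stimulus_id`, `median_rt_s`.
#' @param srt tibble with `participant` and `srt_db`.
#' @param family_size number of tests in the Holm family (default 17).
#' @param bayes_ci compute the promptness credible interval per stimulus
#'   (default TRUE).
#' @param min_n minimum participants per stimulus (default 4).
#' @param seed integer seed for the MCMC.
#' @return tibble with per-stimulus `r_spearman`, `p_raw`, `holm_significant`,
#'   `r_pearson_promptness`, `ci_lo`, `ci_hi`, `ci_excludes_zero`, `n`.
#'   Stimuli with a constant measure are flagged `undefined = TRUE`.
#' @export
spearman_matrix <- function(medians, srt, family_size = 17, bayes_ci = TRUE,
                            min_n = 4, seed = NULL) {
  stopifnot(all(c("participant", "stimulus_id", "median_rt_s") %in% names(medians)),
            all(c("participant", "srt_db") %in% names(srt)))
  joined <- dplyr::inner_join(medians, srt, by = "participant")
  ids <- unique(joined$stimulus_id)
  seeds <- spawn_seeds_(seed %||% sample.int(1e7, 1), length(ids))
  rows <- purrr::map2(ids, seeds, function(id, s) {
    d <- joined[joined$stimulus_id == id &
                  complete.cases(joined[, c("median_rt_s", "srt_db")]), ]
    if (nrow(d) < min_n) {
      return(tibble::tibble(stimulus_id = id, n = nrow(d), undefined = TRUE,
                            r_spearman = NA_real_, p_raw = NA_real_))
    }
    undef <- sd(d$srt_db) == 0 || sd(d$median_rt_s) == 0
    if (undef) {
      return(tibble::tibble(stimulus_id = id, n = nrow(d), undefined = TRUE,
                            r_spearman = NA_real_, p_raw = NA_real_))
    }
    ct <- suppressWarnings(cor.test(d$median_rt_s, d$srt_db,
                                    method = "spearman"))
    out <- tibble::tibble(stimulus_id = id, n = nrow(d), undefined = FALSE,
                          r_spearman = unname(ct$estimate),
                          p_raw = ct$p.value)
    if (bayes_ci) {
      ci <- bayes_pearson_ci(1 / d$median_rt_s, d$srt_db, seed = s)
      out$r_pearson_promptness <- ci$r_mle
      out$ci_lo <- ci$ci[1]
      out$ci_hi <- ci$ci[2]
      out$ci_excludes_zero <- ci$ci[1] > 0 || ci$ci[2] < 0
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  # step-down Holm over the declared family; undefined cells consume no slot
  p <- out$p_raw
  ok <- !is.na(p)
  holm <- rep(NA, length(p))
  if (any(ok)) {
    ord <- order(p[ok])
    thresh <- 0.05 / (family_size - seq_along(ord) + 1)
    sig <- logical(length(ord))
    for (i in seq_along(ord)) {
      if (p[ok][ord[i]] <= thresh[i]) sig[ord[i]] <- TRUE else break
    }
    holm[ok] <- sig
  }
  out$holm_significant <- holm
  out
}

#' Bayesian credible interval for Pearson's correlation
#'
#' Posterior 95% interval for the correlation of a bivariate normal, sampled
#' with a random-walk Metropolis chain on the Fisher z-transform of `r`
#' (uniform prior on `r` over (-1, 1); data standardized so means and scales
#' are profiled out). Defaults follow the convention of 500 burn-in
#' iterations and 1000 retained MCMC samples.
#'
#' @param x,y numeric vectors (n >= 5).
#' @param burn_in,n_samples chain lengths.
#' @param conf interval mass (default 0.95).
#' @param seed integer seed.
#' @return list with `r_mle` (sample correlation), `ci`, `posterior_median`,
#'   `ess` (effective sample size), `ess_warning`.
#' @export
bayes_pearson_ci <- function(x, y, burn_in = 500, n_samples = 1000,
                             conf = 0.95, seed = NULL) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) abort("need at least 5 paired observations",
                   class = "rippleRT_insufficient_data")
  r_hat <- cor(x, y)
  z_cap <- 8 # |rho| < 1 - 1e-6: keeps the posterior proper for degenerate data
  log_post <- function(z) {
    rho <- tanh(z)
    # marginal likelihood of the bivariate-normal correlation given the
    # sample r (location and scale parameters integrated out), plus the
    # Jacobian of the z-parameterization under a uniform prior on rho
    (n - 1) / 2 * log(1 - rho^2) - (n - 1.5) * log(1 - rho * r_hat) +
      log(1 - rho^2)
  }
  prop_sd <- 1.5 / sqrt(max(n - 3, 1))
  draws <- with_seed_(seed, {
    z <- atanh(min(max(r_hat, -0.99), 0.99))
    lp <- log_post(z)
    total <- burn_in + n_samples
    out <- numeric(total)
    for (i in seq_len(total)) {
      z_new <- min(max(z + rnorm(1, 0, prop_sd), -z_cap), z_cap)
      lp_new <- log_post(z_new)
      if (is.finite(lp_new) && log(runif(1)) < lp_new - lp) {
        z <- z_new; lp <- lp_new
      }
      out[i] <- z
    }
    tanh(out[(burn_in + 1):total])
  })
  # crude ESS from the lag-autocorrelation of the chain
  ac <- acf(draws, lag.max = 50, plot = FALSE)$acf[-1]
  pos <- ac[ac > 0.05]
  ess <- n_samples / (1 + 2 * sum(pos))
  list(r_mle = r_hat,
       ci = unname(quantile(draws, c((1 - conf) / 2, 1 - (1 - conf) / 2))),
       posterior_median = median(draws),
       ess = ess, ess_warning = ess < 100)
}

#' Linear and stepwise regression of speech thresholds on age and promptness
#'
#' Fits `SRT = b0 + b1*z(Age) + b2*z(Pr) + b3*[z(Age)*z(Pr)]` by least
#' squares, where `z(Pr)` is the z-scored median promptness over a selected
#' stimulus set. The stepwise variant starts from the intercept-only model,
#' adds the candidate term with the smallest p-value while it is below
#' `p_enter`, then removes terms whose p-value exceeds `p_remove`, iterating
#' to convergence.
#'
#' @param data tibble with columns `age_years`, `promptness`, `srt_db`.
#' @param stepwise run stepwise selection (default FALSE fits the full model).
#' @param p_enter,p_remove stepwise thresholds (0.05 / 0.10).
#' @return an object of class `srt_regression`: `model` (the `lm`),
#'   `coefficients` tibble (term, beta, p), `adjusted_r2`, `selected_terms`,
#'   `stepwise`.
#' @export
fit_srt_regression <- function(data, stepwise = FALSE,
                               p_enter = 0.05, p_remove = 0.10) {
  stopifnot(all(c("age_years", "promptness", "srt_db") %in% names(data)))
  if (any(!complete.cases(data[, c("age_years", "promptness", "srt_db")]))) {
    abort("missing values among included participants",
          class = "rippleRT_data_validation")
  }
  d <- tibble::tibble(
    srt = data$srt_db,
    z_age = as.numeric(scale(data$age_years)),
    z_pr = as.numeric(scale(data$promptness))
  )
  d$z_age_x_pr <- d$z_age * d$z_pr
  if (abs(cor(d$z_age, d$z_pr)) > 0.999) {
    abort("age and promptness are collinear", class = "rippleRT_singular_fit")
  }
  terms_all <- c("z_age", "z_pr", "z_age_x_pr")
  fit_with <- function(terms) {
    fml <- if (length(terms)) {
      stats::reformulate(terms, response = "srt")
    } else {
      srt ~ 1
    }
    lm(fml, data = d)
  }
  term_p <- function(model) {
    cf <- summary(model)$coefficients
    p <- cf[, "Pr(>|t|)"]
    p[setdiff(rownames(cf), "(Intercept)")]
  }
  if (!stepwise) {
    selected <- terms_all
    model <- fit_with(selected)
  } else {
    selected <- character(0)
    repeat {
      changed <- FALSE
      # forward: best candidate below p_enter
      candidates <- setdiff(terms_all, selected)
      if (length(candidates)) {
        p_add <- purrr::map_dbl(candidates, function(tm) {
          term_p(fit_with(c(selected, tm)))[[tm]]
        })
        if (min(p_add) < p_enter) {
          selected <- c(selected, candidates[which.min(p_add)])
          changed <- TRUE
        }
      }
      # backward: drop the worst term above p_remove
      if (length(selected)) {
        p_cur <- term_p(fit_with(selected))[selected]
        if (max(p_cur) > p_remove) {
          selected <- setdiff(selected, names(which.max(p_cur)))
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    model <- fit_with(selected)
  }
  cf <- summary(model)$coefficients
  structure(
    list(model = model,
         coefficients = tibble::tibble(
           term = rownames(cf),
           beta = unname(cf[, "Estimate"]),
           p_value = unname(cf[, "Pr(>|t|)"])),
         adjusted_r2 = summary(model)$adj.r.squared,
         selected_terms = selected,
         stepwise = stepwise),
    class = "srt_regression")
}

#' @export
print.srt_regression <- function(x, ...) {
  cat(sprintf("<srt_regression%s> adjusted R2 %.3f; terms: %s\n",
              if (x$stepwise) " (stepwise)" else "",
              x$adjusted_r2,
              if (length(x$selected_terms)) paste(x$selected_terms, collapse = " + ")
              else "(intercept only)"))
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_srt_regression
#' @param x an `srt_regression` object.
#' @param ... unused.
#' @export
tidy.srt_regression <- function(x, ...) x$coefficients

#' @rdname fit_srt_regression
#' @export
glance.srt_regression <- function(x, ...) {
  tibble::tibble(adjusted_r2 = x$adjusted_r2,
                 n_terms = length(x$selected_terms),
                 stepwise = x$stepwise)
}
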