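#' Bayesian hierarchical model for censored reaction times
#'
#' Bayesian linear model on log reaction time with right-censoring at
#' `log(ceiling_s)`: main effects of implementation, stimulus and participant
#' plus all first-order interactions (sum-to-zero contrasts). Observed trials
#' contribute the normal density; censored trials are treated by data
#' augmentation, imputing their latent log-RT from the truncated normal above
#' the ceiling inside a Gibbs sampler. Priors are weakly informative:
#' coefficients `~ Normal(0, prior_sd^2)` (the intercept gets `10 *
#' prior_sd`), `sigma^2 ~ Inv-Gamma(2, 0.5)`.
#'
#' Factors with a single level (for example one implementation) are dropped
#' from the design, as are interactions involving them.
#'
#' @param clean preprocessed trials from [preprocess_rt()] with columns
#'   `rt_s`, `censored`, and at least two of `implementation`, `stimulus_id`,
#'   `participant`.
#' @param n_iter total Gibbs iterations (default 2000).
#' @param burn_in discarded iterations (default 500).
#' @param prior_sd prior SD of the effect coefficients on the log-RT scale.
#' @param ceiling_s censoring ceiling (default 2.5 s).
#' @param interactions include first-order interactions (default TRUE).
#' @param seed integer seed.
#' @return an object of class `rt_hier_fit`: `effects` tibble with posterior
#'   `mean`, `ci_lo`, `ci_hi` per coefficient and a `group` label (main
#'   effect or interaction it belongs to), `sigma` posterior summary, and the
#'   sampler settings.
#' @export
fit_hierarchical_rt <- function(clean, n_iter = 2000, burn_in = 500,
                                prior_sd = 2.5, ceiling_s = 2.5,
                                interactions = TRUE, seed = NULL) {
  stopifnot(all(c("rt_s", "censored") %in% names(clean)))
  factors <- intersect(c("implementation", "stimulus_id", "participant"),
                       names(clean))
  d <- tibble::as_tibble(clean)
  for (f in factors) d[[f]] <- factor(d[[f]])
  factors <- factors[purrr::map_int(factors, ~ nlevels(d[[.x]])) >= 2]
  if (!length(factors)) {
    fml <- ~ 1
  } else {
    mains <- factors
    pairs <- if (interactions && length(factors) >= 2) {
      utils::combn(factors, 2, FUN = function(p) paste(p, collapse = ":"))
    } else character(0)
    fml <- stats::reformulate(c(mains, pairs))
  }
  contrasts_list <- setNames(
    replicate(length(factors), contr.sum, simplify = FALSE), factors)
  X <- model.matrix(fml, data = d,
                    contrasts.arg = if (length(factors)) contrasts_list else NULL)
  y <- log(d$rt_s)
  cens <- d$censored
  lc <- log(ceiling_s)
  n <- length(y); p <- ncol(X)
  tau <- rep(prior_sd, p)
  tau[colnames(X) == "(Intercept)"] <- 10 * prior_sd
  XtX <- crossprod(X)
  eig <- eigen(XtX, symmetric = TRUE)
  Q <- eig$vectors
  lam <- pmax(eig$values, 0)
  # prior precision is diagonal but not scalar; rotate it once (approximately
  # diagonal in Q for balanced designs, exact when tau is constant) -- use the
  # exact per-iteration solve with a cached rotation for the scalar part and
  # fall back to a full solve when tau varies
  scalar_tau <- length(unique(tau)) == 1
  draws_beta <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, colnames(X)))
  draws_sigma <- numeric(n_iter)
  with_seed_(seed, {
    beta <- qr.solve(XtX + diag(1e-8, p), crossprod(X, y))
    sigma2 <- max(var(y - X %*% beta), 1e-4)
    y_aug <- y
    for (it in seq_len(n_iter)) {
      # impute censored latent log-RTs from the truncated normal above ceiling
      if (any(cens)) {
        mu_c <- as.numeric(X[cens, , drop = FALSE] %*% beta)
        lo <- pnorm(lc, mu_c, sqrt(sigma2))
        u <- runif(sum(cens), lo, 1)
        y_aug[cens] <- qnorm(pmin(u, 1 - 1e-12), mu_c, sqrt(sigma2))
      }
      Xty <- crossprod(X, y_aug)
      if (scalar_tau) {
        dpost <- lam / sigma2 + 1 / tau[1]^2
        m <- Q %*% ((crossprod(Q, Xty) / sigma2) / dpost)
        beta <- m + Q %*% (rnorm(p) / sqrt(dpost))
      } else {
        prec <- XtX / sigma2 + diag(1 / tau^2)
        ch <- chol(prec)
        m <- backsolve(ch, forwardsolve(t(ch), Xty / sigma2))
        beta <- m + backsolve(ch, rnorm(p))
      }
      resid <- y_aug - X %*% beta
      sigma2 <- 1 / rgamma(1, shape = 2 + n / 2,
                           rate = 0.5 + sum(resid^2) / 2)
      draws_beta[it, ] <- beta
      draws_sigma[it] <- sqrt(sigma2)
    }
  })
  keep <- (burn_in + 1):n_iter
  bk <- draws_beta[keep, , drop = FALSE]
  group_of <- function(nm) {
    if (nm == "(Intercept)") return("intercept")
    hits <- factors[purrr::map_lgl(factors, ~ grepl(.x, nm, fixed = TRUE))]
    if (grepl(":", nm, fixed = TRUE)) paste(hits, collapse = ":")
    else hits[1]
  }
  effects <- tibble::tibble(
    term = colnames(X),
    group = purrr::map_chr(colnames(X), group_of),
    mean = colMeans(bk),
    ci_lo = apply(bk, 2, quantile, 0.025),
    ci_hi = apply(bk, 2, quantile, 0.975)
  )
  structure(
    list(effects = effects,
         sigma = tibble::tibble(mean = mean(draws_sigma[keep]),
                                ci_lo = quantile(draws_sigma[keep], 0.025),
                                ci_hi = quantile(draws_sigma[keep], 0.975)),
         draws = bk,
         formula = fml,
         n_iter = n_iter, burn_in = burn_in,
         ceiling_s = ceiling_s,
         n = n, n_censored = sum(cens)),
    class = "rt_hier_fit")
}

#' @export
print.rt_hier_fit <- function(x, ...) {
  cat(sprintf("<rt_hier_fit> censored log-RT model: %d trials (%d censored), %d coefficients\n",
              x$n, x$n_censored, nrow(x$effects)))
  print(dplyr::count(x$effects, .data$group))
  invisible(x)
}

#' @rdname fit_hierarchical_rt
#' @param x an `rt_hier_fit` object.
#' @param ... unused.
#' @export
tidy.rt_hier_fit <- function(x, ...) x$effects

#' @rdname fit_hierarchical_rt
#' @export
glance.rt_hier_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_censored = x$n_censored,
                 sigma = x$sigma$mean, n_iter = x$n_iter,
                 burn_in = x$burn_in)
}
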