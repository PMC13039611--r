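test_that("Spearman cells handle monotone, reciprocal and degenerate inputs", {
  med <- tibble::tibble(
    participant = sprintf("S%02d", 1:8),
    stimulus_id = "bb_0Hz_0.25co",
    median_rt_s = c(0.3, 0.4, 0.5, 0.7, 0.9, 1.2, 1.6, 2.1)
  )
  srt <- tibble::tibble(participant = med$participant,
                        srt_db = seq(-4, 10, length.out = 8))
  cells <- spearman_matrix(med, srt, bayes_ci = FALSE)
  expect_equal(cells$r_spearman, 1)
  # rank reversal under the reciprocal transform: equal magnitude, flipped sign
  cells_p <- spearman_matrix(dplyr::mutate(med, median_rt_s = 1 / median_rt_s),
                             srt, bayes_ci = FALSE)
  expect_equal(cells_p$r_spearman, -1)
  # constant thresholds are flagged undefined
  cells_c <- spearman_matrix(med, dplyr::mutate(srt, srt_db = 1),
                             bayes_ci = FALSE)
  expect_true(cells_c$undefined)
})

test_that("Holm step-down uses the family-size thresholds", {
  # family of 17 with smallest p = 0.002: first Holm threshold is 0.05/17
  meds <- purrr::map(1:17, function(i) {
    tibble::tibble(participant = sprintf("S%02d", 1:10),
                   stimulus_id = paste0("stim", i),
                   median_rt_s = withr::with_seed(i, runif(10)))
  }) |> dplyr::bind_rows()
  srt <- tibble::tibble(participant = sprintf("S%02d", 1:10),
                        srt_db = withr::with_seed(99, rnorm(10)))
  cells <- spearman_matrix(meds, srt, family_size = 17, bayes_ci = FALSE)
  # verify against direct Holm arithmetic on the same p-values
  p <- cells$p_raw
  ord <- order(p)
  manual <- logical(17)
  for (i in seq_along(ord)) {
    if (p[ord[i]] <= 0.05 / (17 - i + 1)) manual[ord[i]] <- TRUE else break
  }
  expect_equal(cells$holm_significant, manual)
  expect_equal(0.05 / 17, 0.00294, tolerance = 1e-3)
  expect_true(all(p[cells$holm_significant] <= 0.05)) # Holm subset of raw
})

test_that("Holm correction controls the family-wise error rate", {
  n_rep <- 400
  fwer <- withr::with_seed(1, mean(replicate(n_rep, {
    srt <- rnorm(19)
    p <- vapply(1:17, function(i) {
      suppressWarnings(cor.test(rnorm(19), srt, method = "spearman")$p.value)
    }, 0)
    any(p.adjust(p, "holm") <= 0.05)
  })))
  expect_lte(fwer, 0.07)
})

test_that("the Bayesian correlation interval is calibrated and concentrates", {
  # null coverage at moderate n
  cover <- withr::with_seed(2, mean(replicate(150, {
    ci <- bayes_pearson_ci(rnorm(40), rnorm(40), seed = sample.int(1e6, 1))$ci
    ci[1] <= 0 && ci[2] >= 0
  })))
  expect_gt(cover, 0.88)
  expect_lte(cover, 1)
  # recovery at the canonical cohort size
  meds <- withr::with_seed(3, replicate(60, {
    z <- rnorm(19)
    x <- 0.65 * z + rnorm(19) * sqrt(1 - 0.65^2)
    bayes_pearson_ci(x, z, seed = sample.int(1e6, 1))$posterior_median
  }))
  expect_equal(mean(meds), 0.65, tolerance = 0.15 / 0.65)
  # perfectly linear data concentrate at +1
  ci <- bayes_pearson_ci(1:20, 2 * (1:20) + 3, seed = 4)
  expect_gt(ci$ci[1], 0.95)
  expect_error(bayes_pearson_ci(1:4, 1:4), class = "rippleRT_insufficient_data")
})

test_that("the SRT regression recovers generating coefficients", {
  # promptness-only generator at the canonical cohort size
  b2 <- withr::with_seed(5, mean(replicate(120, {
    d <- tibble::tibble(age_years = runif(19, 40, 80),
                        promptness = rnorm(19, 1.5, 0.4))
    d$srt_db <- -0.69 * as.numeric(scale(d$promptness)) + rnorm(19, 0, 0.5)
    fit <- fit_srt_regression(d)
    fit$coefficients$beta[fit$coefficients$term == "z_pr"]
  })))
  expect_equal(b2, -0.69, tolerance = 0.1 / 0.69)

  # noise-free three-term generator is recovered exactly
  d <- withr::with_seed(6, tibble::tibble(age_years = runif(19, 40, 80),
                                          promptness = rnorm(19, 1.5, 0.4)))
  za <- as.numeric(scale(d$age_years)); zp <- as.numeric(scale(d$promptness))
  d$srt_db <- 2 + 0.5 * za - 0.7 * zp - 0.4 * za * zp
  fit <- suppressWarnings(fit_srt_regression(d)) # lm flags the perfect fit
  cf <- setNames(fit$coefficients$beta, fit$coefficients$term)
  expect_equal(unname(cf[c("z_age", "z_pr", "z_age_x_pr")]),
               c(0.5, -0.7, -0.4), tolerance = 1e-8)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-8)
  # intercept of the standardized fit is the threshold mean
  expect_equal(unname(cf["(Intercept)"]), mean(d$srt_db), tolerance = 0.2)
})

test_that("stepwise selection keeps the generating term", {
  picks <- withr::with_seed(7, replicate(60, {
    d <- tibble::tibble(age_years = runif(30, 40, 80),
                        promptness = rnorm(30, 1.5, 0.4))
    d$srt_db <- 1.5 * as.numeric(scale(d$age_years)) + rnorm(30, 0, 0.6)
    fit <- fit_srt_regression(d, stepwise = TRUE)
    identical(fit$selected_terms, "z_age")
  }))
  expect_gt(mean(picks), 0.8)
  # missing values are refused
  bad <- tibble::tibble(age_years = c(50, NA), promptness = 1:2, srt_db = 1:2)
  expect_error(fit_srt_regression(bad), class = "rippleRT_data_validation")
})

test_that("participant-label permutation leaves the regression invariant", {
  d <- withr::with_seed(8, tibble::tibble(age_years = runif(15, 40, 80),
                                          promptness = rnorm(15, 1.5, 0.3)))
  d$srt_db <- withr::with_seed(9, 3 - 1.2 * scale(d$promptness)[, 1] + rnorm(15, 0, 0.4))
  f1 <- fit_srt_regression(d)
  perm <- withr::with_seed(10, sample(nrow(d)))
  f2 <- fit_srt_regression(d[perm, ])
  expect_equal(f1$coefficients$beta, f2$coefficients$beta, tolerance = 1e-10)
  expect_equal(f1$adjusted_r2, f2$adjusted_r2, tolerance = 1e-12)
})

test_that("the hierarchical censored model is calibrated under the null", {
  make_null <- function(seed) {
    withr::with_seed(seed, {
      g <- tidyr::expand_grid(participant = paste0("S", 1:5),
                              implementation = c("App", "Laptop"),
                              stimulus_id = c("a", "b", "c"), trial = 1:8)
      mu <- log(0.7) + 0.25 * (g$stimulus_id == "a") +
        0.1 * as.integer(factor(g$participant))
      rt <- exp(rnorm(nrow(g), mu, 0.3))
      cens <- rt > 2.5
      rt[cens] <- 2.5
      tibble::tibble(participant = g$participant,
                     implementation = g$implementation,
                     stimulus_id = g$stimulus_id, rt_s = rt, censored = cens)
    })
  }
  hits <- vapply(1:12, function(s) {
    f <- fit_hierarchical_rt(make_null(s), n_iter = 700, burn_in = 200,
                             seed = s)
    imp <- dplyr::filter(f$effects, group == "implementation")
    imp$ci_lo <= 0 && imp$ci_hi >= 0
  }, TRUE)
  expect_gte(mean(hits), 10 / 12)
})

test_that("a configured implementation-by-stimulus effect is recovered in sign", {
  clean <- withr::with_seed(20, {
    g <- tidyr::expand_grid(participant = paste0("S", 1:6),
                            implementation = c("App", "Laptop"),
                            stimulus_id = c("a", "b", "c", "d"), trial = 1:10)
    mu <- log(0.6) + 0.2 * (g$stimulus_id %in% c("b", "d")) +
      0.12 * as.integer(factor(g$participant)) +
      0.18 * (g$implementation == "App" & g$stimulus_id == "a")
    rt <- exp(rnorm(nrow(g), mu, 0.25))
    cens <- rt > 2.5
    rt[cens] <- 2.5
    tibble::tibble(participant = g$participant,
                   implementation = g$implementation,
                   stimulus_id = g$stimulus_id, rt_s = rt, censored = cens)
  })
  f <- fit_hierarchical_rt(clean, n_iter = 1200, burn_in = 300, seed = 21)
  inter <- dplyr::filter(f$effects, group == "implementation:stimulus_id",
                         grepl("stimulus_id1", term))
  # App coded +1, stimulus "a" is level 1: the slowed App-on-a cell shows as a
  # positive interaction that excludes zero
  expect_gt(inter$mean, 0)
  expect_gt(inter$ci_lo, 0)
})

test_that("a single cell reduces to the censored location estimate", {
  smp <- censored_later_sample(later_params(0.8, 0.2), 400, seed = 22)
  clean <- make_clean_tbl(smp$rt, smp$censored)
  f <- fit_hierarchical_rt(clean, n_iter = 1500, burn_in = 500, seed = 23)
  mu_log <- unname(f$effects$mean[f$effects$term == "(Intercept)"])
  later <- fit_later(smp$rt, smp$censored)
  # both models estimate the median reaction time of the same data
  expect_equal(exp(mu_log), 1 / later$mu_p_hat, tolerance = 0.05)
})
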