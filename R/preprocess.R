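#' Censor, floor and flag raw reaction times
#'
#' Implements the canonical reaction-time preprocessing rules: reaction times
#' exceeding the ceiling, and non-responses, are coded *at* the ceiling with a
#' censored flag; responses faster than the floor are removed (the floor is
#' exclusive: a response at exactly `floor_s` is retained) and counted as fast
#' guesses. An optional fixed technical delay is first subtracted from the
#' reaction times of one implementation (the ceiling applies after delay
#' correction, so a corrected response may fall below the floor and is then
#' removed).
#'
#' @param trials trial table with at least `rt_raw_s` (NA for non-response)
#'   and `responded`; typically the `trials` element of [simulate_cohort()].
#' @param ceiling_s censoring ceiling in seconds (default 2.5).
#' @param floor_s fast-guess floor in seconds (default 0.140).
#' @param delay_s technical delay to subtract before censoring (default 0).
#' @param delay_implementation which `implementation` level the delay applies
#'   to (default `"App"`); ignored when `delay_s = 0` or the column is absent.
#' @return a tibble of retained trials with columns `rt_s` (delay-corrected,
#'   censored) and `censored`, plus attributes `n_removed_fast` and
#'   `n_censored`. Rows removed as fast guesses are dropped.
#' @export
preprocess_rt <- function(trials, ceiling_s = 2.5, floor_s = 0.140,
                          delay_s = 0, delay_implementation = "App") {
  stopifnot(is.data.frame(trials), "rt_raw_s" %in% names(trials))
  rt <- trials$rt_raw_s
  if (any(rt < 0, na.rm = TRUE)) {
    abort("negative reaction times in input", class = "rippleRT_data_validation")
  }
  out <- tibble::as_tibble(trials)
  if (delay_s != 0 && "implementation" %in% names(out)) {
    is_delayed <- out$implementation == delay_implementation
    rt <- rt - delay_s * is_delayed
  }
  responded <- if ("responded" %in% names(out)) out$responded else !is.na(rt)
  censored <- !responded | is.na(rt) | rt > ceiling_s
  fast <- !censored & rt < floor_s
  rt_clean <- ifelse(censored, ceiling_s, rt)
  out$rt_s <- rt_clean
  out$censored <- censored
  out <- out[!fast, , drop = FALSE]
  attr(out, "n_removed_fast") <- sum(fast)
  attr(out, "n_censored") <- sum(censored)
  attr(out, "ceiling_s") <- ceiling_s
  attr(out, "floor_s") <- floor_s
  out
}

#' Check block homogeneity with two-sample Kolmogorov-Smirnov tests
#'
#' For every (participant, implementation, stimulus) cell with two measurement
#' blocks, tests whether the two blocks' reaction-time distributions could
#' come from the same distribution. Blocks are pooled downstream regardless;
#' the test flags cells where pooling deserves scrutiny.
#'
#' @param clean preprocessed trials from [preprocess_rt()] with a `block`
#'   column.
#' @return tibble with one row per cell: `ks_d`, `p_value`, `n1`, `n2`.
#' @export
block_homogeneity <- function(clean) {
  stopifnot(all(c("block", "rt_s") %in% names(clean)))
  key <- intersect(c("participant", "implementation", "stimulus_id"), names(clean))
  clean |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::group_modify(function(d, g) {
      b <- sort(unique(d$block))
      if (length(b) < 2) {
        abort("block_homogeneity needs two blocks per cell",
              class = "rippleRT_undefined_test")
      }
      x <- d$rt_s[d$block == b[1]]
      y <- d$rt_s[d$block == b[2]]
      if (!length(x) || !length(y)) {
        abort("empty block in a cell", class = "rippleRT_undefined_test")
      }
      ks <- suppressWarnings(ks.test(x, y, exact = FALSE))
      tibble::tibble(ks_d = unname(ks$statistic), p_value = ks$p.value,
                     n1 = length(x), n2 = length(y))
    }) |>
    dplyr::ungroup()
}

#' Pool blocks and compute median reaction times
#'
#' Pools the retained trials of all blocks within each (participant,
#' implementation, stimulus) cell and computes the median reaction time over
#' the pooled values, censored codes included, plus the median promptness
#' (1/median RT). Cells whose every trial is censored are flagged.
#'
#' @param clean preprocessed trials from [preprocess_rt()].
#' @return tibble with `median_rt_s`, `promptness`, `n`, `n_censored`,
#'   `fully_censored` per cell. Cells with zero retained trials yield `NA`
#'   medians rather than an error.
#' @export
pool_median <- function(clean) {
  stopifnot(all(c("rt_s", "censored") %in% names(clean)))
  key <- intersect(c("participant", "implementation", "stimulus_id"), names(clean))
  clean |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(
      median_rt_s = if (dplyr::n() == 0) NA_real_ else median(.data$rt_s),
      n = dplyr::n(),
      n_censored = sum(.data$censored),
      fully_censored = all(.data$censored),
      .groups = "drop"
    ) |>
    dplyr::mutate(promptness = 1 / .data$median_rt_s)
}

#' Estimate the technical delay between implementations
#'
#' Per participant and reference stimulus, takes the App minus Laptop
#' difference of pooled median reaction times; the group-level mean over all
#' such differences is the delay estimate. Participants missing a median for
#' any reference stimulus in either implementation are excluded and reported.
#'
#' @param medians output of [pool_median()] covering both implementations.
#' @param ref_stimuli stimulus ids of the well-perceived reference conditions
#'   (default [delay_reference_stimuli()]).
#' @return an object of class `delay_estimate`: a list with `delay_s` (the
#'   group-level mean), `by_participant` (per participant-stimulus
#'   differences) and `excluded` (participants dropped).
#' @export
estimate_delay <- function(medians, ref_stimuli = delay_reference_stimuli()) {
  stopifnot(all(c("participant", "implementation", "stimulus_id", "median_rt_s")
                %in% names(medians)))
  wide <- medians |>
    dplyr::filter(.data$stimulus_id %in% ref_stimuli) |>
    dplyr::select("participant", "implementation", "stimulus_id", "median_rt_s") |>
    tidyr::pivot_wider(names_from = "implementation", values_from = "median_rt_s")
  if (!all(c("App", "Laptop") %in% names(wide))) {
    abort("medians must cover both the App and Laptop implementations",
          class = "rippleRT_data_validation")
  }
  complete <- wide |>
    dplyr::group_by(.data$participant) |>
    dplyr::filter(dplyr::n() == length(ref_stimuli),
                  !any(is.na(.data$App)), !any(is.na(.data$Laptop))) |>
    dplyr::ungroup() |>
    dplyr::mutate(diff_s = .data$App - .data$Laptop)
  excluded <- setdiff(unique(wide$participant), unique(complete$participant))
  if (!nrow(complete)) {
    abort("no participant has all reference stimuli in both implementations",
          class = "rippleRT_data_validation")
  }
  structure(list(delay_s = mean(complete$diff_s),
                 by_participant = complete,
                 ref_stimuli = ref_stimuli,
                 excluded = excluded),
            class = "delay_estimate")
}

#' @export
print.delay_estimate <- function(x, ...) {
  cat(sprintf("<delay_estimate> %.1f ms (mean of %d participant x stimulus differences)\n",
              1000 * x$delay_s, nrow(x$by_participant)))
  if (length(x$excluded)) {
    cat(" excluded participants:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Full preprocessing chain with delay alignment
#'
#' Convenience wrapper running the canonical pipeline: preprocess the raw
#' trials without delay correction, estimate the App-vs-Laptop technical delay
#' from the three reference stimuli, re-preprocess the raw trials with the
#' estimated delay subtracted from App reaction times, and pool medians.
#'
#' @param trials raw trial table (see [preprocess_rt()]).
#' @param ref_stimuli reference stimuli for [estimate_delay()].
#' @param ... passed to [preprocess_rt()].
#' @return list with `clean` (delay-corrected preprocessed trials), `medians`,
#'   and `delay` (the [estimate_delay()] object).
#' @export
rt_pipeline <- function(trials, ref_stimuli = delay_reference_stimuli(), ...) {
  clean0 <- preprocess_rt(trials, ...)
  delay <- estimate_delay(pool_median(clean0), ref_stimuli)
  clean <- preprocess_rt(trials, delay_s = delay$delay_s, ...)
  list(clean = clean, medians = pool_median(clean), delay = delay)
}
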