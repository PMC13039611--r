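#' Reciprobit plot for one or more fitted reaction-time sets
#'
#' Plots cumulative response probability on a probit scale against promptness
#' (axis reversed and labeled in reaction-time units, so fast responses sit on
#' the left), with the fitted LATER line overlaid.
#'
#' @param object a [fit_later()] object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.later_fit <- function(object, ...) {
  pts <- object$points
  line_df <- tibble::tibble(
    promptness = seq(min(pts$promptness) * 0.8, max(pts$promptness) * 1.2,
                     length.out = 50)
  )
  line_df$probit <- (object$mu_p_hat - line_df$promptness) / object$sigma_p_hat
  breaks_rt <- c(0.2, 0.3, 0.5, 1, 2.5)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$promptness, y = .data$probit)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_line(data = line_df, color = "steelblue") +
    ggplot2::scale_x_reverse(breaks = 1 / breaks_rt,
                             labels = paste0(breaks_rt, " s")) +
    ggplot2::scale_y_continuous(
      breaks = qnorm(c(0.05, 0.25, 0.5, 0.75, 0.95)),
      labels = c("5%", "25%", "50%", "75%", "95%")) +
    ggplot2::labs(x = "reaction time (promptness scale)",
                  y = "cumulative probability (probit scale)") +
    ggplot2::theme_minimal()
}

#' Plot reciprobit overlays per stimulus
#'
#' Overlays the reciprobit point clouds of several stimuli for one
#' participant and implementation, the standard view of how stimulus
#' difficulty orders a listener's response distributions.
#'
#' @param clean preprocessed trials from [preprocess_rt()] restricted to one
#'   participant and implementation.
#' @param stimuli stimulus ids to include (default: all broadband).
#' @return a ggplot.
#' @export
plot_reciprobit_overlay <- function(clean, stimuli = NULL) {
  stopifnot(all(c("stimulus_id", "rt_s", "censored") %in% names(clean)))
  stimuli <- stimuli %||%
    grep("^bb_", unique(clean$stimulus_id), value = TRUE)
  pts <- purrr::map(stimuli, function(id) {
    d <- clean[clean$stimulus_id == id, ]
    if (sum(!d$censored) < 2) return(NULL)
    dplyr::mutate(reciprobit_points(d$rt_s, d$censored), stimulus_id = id)
  }) |>
    dplyr::bind_rows()
  breaks_rt <- c(0.2, 0.3, 0.5, 1, 2.5)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$promptness, y = .data$probit,
                                    color = .data$stimulus_id)) +
    ggplot2::geom_point(shape = 1, alpha = 0.8) +
    ggplot2::scale_x_reverse(breaks = 1 / breaks_rt,
                             labels = paste0(breaks_rt, " s")) +
    ggplot2::scale_y_continuous(
      breaks = qnorm(c(0.05, 0.25, 0.5, 0.75, 0.95)),
      labels = c("5%", "25%", "50%", "75%", "95%")) +
    ggplot2::labs(x = "reaction time (promptness scale)",
                  y = "cumulative probability (probit scale)",
                  color = "stimulus") +
    ggplot2::theme_minimal()
}

#' Modulation-transfer-function plots
#'
#' Spectral view (mean value against spectral density, one line per temporal
#' rate) and temporal view (against rate, one line per density) of an
#' [mtf()] table, with the reaction-time axis reversed so faster (more
#' sensitive) sits higher.
#'
#' @param object an `mtf_table` from [mtf()].
#' @param view `"spectral"`, `"temporal"` or `"narrowband"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mtf_table <- function(object, view = c("spectral", "temporal",
                                                "narrowband"), ...) {
  view <- match.arg(view)
  scale <- attr(object, "scale") %||% "rt"
  ylab <- if (scale == "rt") "mean reaction time (s)" else "mean promptness (1/s)"
  if (view == "narrowband") {
    d <- dplyr::filter(object, .data$band_kind == "narrowband")
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$cf_hz, y = .data$mean_value)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                            ymax = .data$ci_hi)) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "center frequency (Hz)", y = ylab)
  } else {
    d <- dplyr::filter(object, .data$band_kind == "broadband")
    if (view == "spectral") {
      p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$omega, y = .data$mean_value,
                                           color = factor(.data$rate_hz),
                                           group = factor(.data$rate_hz)))
      p <- p + ggplot2::labs(x = "spectral density (cycles/octave)", y = ylab,
                             color = "rate (Hz)")
    } else {
      p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rate_hz, y = .data$mean_value,
                                           color = factor(.data$omega),
                                           group = factor(.data$omega)))
      p <- p + ggplot2::labs(x = "temporal rate (Hz)", y = ylab,
                             color = "density (c/o)")
    }
    p <- p + ggplot2::geom_line() +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                            ymax = .data$ci_hi))
  }
  if (scale == "rt") p <- p + ggplot2::scale_y_reverse()
  p + ggplot2::theme_minimal()
}

#' Heatmap of correlations between reaction times and speech thresholds
#'
#' Correlation matrix view of [spearman_matrix()] results: stimuli laid out
#' on the canonical grid (narrowband row over center frequency, broadband
#' rows density by rate), colored by Spearman's r, with markers for credible
#' intervals excluding zero and for Holm-corrected significance.
#'
#' @param cells output of [spearman_matrix()], optionally with an
#'   `implementation` column for faceting.
#' @return a ggplot.
#' @export
plot_correlation_heatmap <- function(cells) {
  grid <- dplyr::select(stimulus_table(), "stimulus_id", "band_kind",
                        "rate_hz", "omega", "cf_hz")
  if (!"ci_excludes_zero" %in% names(cells)) cells$ci_excludes_zero <- NA
  d <- dplyr::inner_join(cells, grid, by = "stimulus_id") |>
    dplyr::mutate(
      row = ifelse(.data$band_kind == "narrowband", "narrowband",
                   paste0(.data$omega, " c/o")),
      col = ifelse(.data$band_kind == "narrowband",
                   paste0(.data$cf_hz, " Hz"), paste0(.data$rate_hz, " Hz")),
      label = dplyr::case_when(
        !is.na(.data$holm_significant) & .data$holm_significant ~ "***",
        !is.na(.data$ci_excludes_zero) & .data$ci_excludes_zero ~ "*",
        TRUE ~ ""
      ))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$r_spearman)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label)) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman r") +
    ggplot2::theme_minimal()
  if ("implementation" %in% names(cells)) {
    p <- p + ggplot2::facet_wrap(~implementation)
  }
  p
}
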