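#' Define one ripple stimulus condition
#'
#' A ripple spec describes a single spectrotemporal ripple-in-noise condition:
#' the modulated band (broadband 250--8000 Hz or a 1-octave narrowband), the
#' spectral modulation density `omega` (cycles/octave), the temporal modulation
#' rate `rate_hz` (Hz), the modulation depth, and the level accentuation of the
#' modulated band relative to the surrounding noise.
#'
#' The catch condition carries the full carrier and accentuation but zero
#' modulation (`omega = 0`, `rate_hz = 0`); all other processing is identical.
#'
#' @param band_kind one of `"broadband"`, `"narrowband"`, `"catch"`.
#' @param f_lo,f_hi modulated-band edges in Hz. Defaults: broadband (and catch)
#'   250--8000 Hz; for narrowband specs give `cf` instead.
#' @param cf geometric center frequency of a 1-octave narrowband ripple
#'   (one of 500, 1000, 2000, 4000 in the canonical set); sets
#'   `f_lo = cf/sqrt(2)`, `f_hi = cf*sqrt(2)`.
#' @param omega spectral density in cycles/octave (>= 0).
#' @param rate_hz temporal modulation rate in Hz (>= 0).
#' @param depth modulation depth `m` in `[0, 1]`, applied on a linear amplitude
#'   scale as `1 + m*sin(...)`. Default 0.82.
#' @param accent_db level accentuation of the modulated band in dB. Default 15.
#' @param phase0 starting phase in radians at `f_lo` and modulation onset.
#' @param omega_sign +1 (default) for a downward-drifting ripple when both
#'   `rate_hz` and `omega` are positive; -1 for upward.
#' @return an object of class `ripple_spec`.
#' @examples
#' ripple_spec("broadband", omega = 0.5, rate_hz = 4)
#' ripple_spec("narrowband", cf = 1000, omega = 2, rate_hz = 4)
#' @export
ripple_spec <- function(band_kind = c("broadband", "narrowband", "catch"),
                        f_lo = NULL, f_hi = NULL, cf = NULL,
                        omega = 0, rate_hz = 0, depth = 0.82,
                        accent_db = 15, phase0 = 0, omega_sign = 1) {
  band_kind <- match.arg(band_kind)
  assert_scalar_num_(omega, "omega", lower = 0)
  assert_scalar_num_(rate_hz, "rate_hz", lower = 0)
  assert_scalar_num_(depth, "depth", lower = 0, upper = 1)
  assert_scalar_num_(accent_db, "accent_db")
  if (!omega_sign %in% c(-1, 1)) {
    abort("`omega_sign` must be +1 or -1", class = "rippleRT_invalid_configuration")
  }
  if (band_kind == "narrowband") {
    if (is.null(cf) && (is.null(f_lo) || is.null(f_hi))) {
      abort("narrowband specs need `cf` or both band edges",
            class = "rippleRT_invalid_configuration")
    }
    if (!is.null(cf)) {
      f_lo <- cf / sqrt(2)
      f_hi <- cf * sqrt(2)
    }
    if (abs(f_hi / f_lo - 2) > 1e-9) {
      abort("narrowband ripples span exactly one octave (f_hi = 2 * f_lo)",
            class = "rippleRT_invalid_configuration")
    }
  } else {
    f_lo <- f_lo %||% 250
    f_hi <- f_hi %||% 8000
    if (band_kind == "catch" && (omega != 0 || rate_hz != 0)) {
      abort("catch specs have omega = 0 and rate_hz = 0",
            class = "rippleRT_invalid_configuration")
    }
  }
  if (f_lo >= f_hi) {
    abort("f_lo must be below f_hi", class = "rippleRT_invalid_configuration")
  }
  structure(
    list(band_kind = band_kind, f_lo = f_lo, f_hi = f_hi,
         omega = omega, rate_hz = rate_hz, depth = depth,
         accent_db = accent_db, phase0 = phase0, omega_sign = omega_sign),
    class = "ripple_spec"
  )
}

#' @export
print.ripple_spec <- function(x, ...) {
  cat(sprintf("<ripple_spec> %s [%g Hz, %g c/o] band %.0f-%.0f Hz, depth %.2f, accent %g dB\n",
              x$band_kind, x$rate_hz, x$omega, x$f_lo, x$f_hi, x$depth, x$accent_db))
  invisible(x)
}

# short machine id used as the stimulus key throughout trial tables
spec_id_ <- function(spec) {
  if (spec$band_kind == "catch") return("bb_catch")
  if (spec$band_kind == "narrowband") {
    cf <- sqrt(spec$f_lo * spec$f_hi)
    return(sprintf("nb_%gHz", round(cf)))
  }
  sprintf("bb_%gHz_%gco", spec$rate_hz, spec$omega)
}

#' The canonical 17-condition stimulus table
#'
#' Builds the full canonical stimulus set: four 1-octave narrowband ripples
#' (centered at 500, 1000, 2000 and 4000 Hz, all modulated at 4 Hz and
#' 2 cycles/octave), twelve modulated broadband conditions spanning temporal
#' rates 0--16 Hz and spectral densities 0--2 cycles/octave, and one broadband
#' catch condition with zero modulation.
#'
#' @param depth,accent_db passed to every [ripple_spec()].
#' @return a tibble with one row per condition: `stimulus_id`, `band_kind`,
#'   `rate_hz`, `omega`, `cf_hz` (narrowband center, `NA` otherwise), `f_lo`,
#'   `f_hi`, and a list-column `spec` of `ripple_spec` objects.
#' @examples
#' stimulus_table()
#' @export
stimulus_table <- function(depth = 0.82, accent_db = 15) {
  nb <- purrr::map(c(500, 1000, 2000, 4000), function(cf) {
    ripple_spec("narrowband", cf = cf, omega = 2, rate_hz = 4,
                depth = depth, accent_db = accent_db)
  })
  bb_grid <- list(
    c(0, 2), c(0, 1), c(0, 0.5), c(0, 0.25),
    c(4, 2), c(4, 1), c(4, 0.5), c(4, 0),
    c(8, 1), c(8, 0.5), c(8, 0),
    c(16, 0.25)
  )
  bb <- purrr::map(bb_grid, function(g) {
    ripple_spec("broadband", omega = g[2], rate_hz = g[1],
                depth = depth, accent_db = accent_db)
  })
  specs <- c(nb, bb, list(ripple_spec("catch", depth = depth, accent_db = accent_db)))
  tibble::tibble(
    stimulus_id = purrr::map_chr(specs, spec_id_),
    band_kind = purrr::map_chr(specs, "band_kind"),
    rate_hz = purrr::map_dbl(specs, "rate_hz"),
    omega = purrr::map_dbl(specs, "omega"),
    cf_hz = purrr::map_dbl(specs, function(s) {
      if (s$band_kind == "narrowband") round(sqrt(s$f_lo * s$f_hi)) else NA_real_
    }),
    f_lo = purrr::map_dbl(specs, "f_lo"),
    f_hi = purrr::map_dbl(specs, "f_hi"),
    spec = specs
  )
}

#' The three well-perceived reference stimuli used for delay alignment
#'
#' Stimulus ids of the three broadband conditions to which essentially all
#' listeners respond quickly and reliably; differences in their median reaction
#' times between delivery implementations estimate the technical delay.
#'
#' @return character vector of three stimulus ids.
#' @export
delay_reference_stimuli <- function() {
  c("bb_4Hz_0.5co", "bb_8Hz_0co", "bb_16Hz_0.25co")
}
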