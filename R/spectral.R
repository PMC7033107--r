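# Spectral description of coordination patterns: one-sided periodogram of
# vertical hand velocity and the Coordination Pattern Index (CPI), the
# proportion of spectral power concentrated at the fundamental movement
# frequency. Rhythmic patterns put nearly all velocity power at the
# fundamental; discrete move-and-dwell patterns spread power into
# harmonics, so the CPI falls.

#' One-sided periodogram
#'
#' Plain (rectangular-window) periodogram of a uniformly sampled signal.
#' Power is scaled so that the sum over the non-DC bins equals the mean
#' squared deviation of the signal from its mean (Parseval), making the
#' CPI a true proportion of variance.
#'
#' @param signal a [sampled_signal()], length >= 64.
#' @return an object of class `spectral_density` with fields `freqs`
#'   (Hz, ascending from 0), `power`, `resolution` (Hz bin width).
#' @export
power_spectrum <- function(signal) {
  stopifnot(inherits(signal, "sampled_signal"))
  x <- signal$values
  n <- length(x)
  if (n < 64) stop_parameter("power_spectrum needs at least 64 samples")
  X <- fft(x)
  nf <- floor(n / 2) + 1L
  p <- (Mod(X[seq_len(nf)])^2) / n^2
  # double the interior one-sided bins (DC and, for even n, Nyquist appear once)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  p <- p * dbl
  freqs <- (seq_len(nf) - 1L) * signal$rate / n
  structure(list(freqs = freqs, power = p, resolution = signal$rate / n),
            class = "spectral_density")
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf("<spectral_density: %d bins, resolution %.4g Hz>\n",
              length(x$freqs), x$resolution))
  invisible(x)
}

#' Fundamental movement frequency
#'
#' For metronome-paced trials the fundamental frequency of one hand's
#' movement is derived from the beep interval: catches alternate hands,
#' so each hand completes one full cycle every two beeps and
#' `f0 = 1 / (2 * interval)` (the alternative `f0 = 1 / interval`
#' convention is selectable). For free-tempo trials the fundamental is
#' the frequency of the largest non-DC periodogram peak of that hand's
#' vertical velocity.
#'
#' @param beeps a fixed-tempo [make_beep_train()], or `NULL`.
#' @param signal a [sampled_signal()] of vertical velocity; required when
#'   `beeps` is `NULL` or a free-tempo train.
#' @param convention `"half_beep_rate"` (default) or `"beep_rate"`.
#' @return fundamental frequency, Hz.
#' @export
fundamental_frequency <- function(beeps = NULL, signal = NULL,
                                  convention = c("half_beep_rate", "beep_rate")) {
  convention <- match.arg(convention)
  if (!is.null(beeps) && inherits(beeps, "beep_train") &&
      beeps$condition == "fixed") {
    int_s <- beeps$interval_ms / 1000
    return(if (convention == "half_beep_rate") 1 / (2 * int_s) else 1 / int_s)
  }
  if (!is.null(beeps) && inherits(beeps, "beep_train") &&
      beeps$condition %in% c("up_ramp", "down_ramp"))
    stop_parameter("fundamental frequency is undefined for ramped beep trains")
  if (is.null(signal))
    stop_parameter("free-tempo trials need a velocity signal for peak picking")
  ps <- power_spectrum(signal)
  nz <- ps$freqs > 0
  ps$freqs[nz][which.max(ps$power[nz])]
}

#' Coordination Pattern Index
#'
#' Proportion of spectral power within a narrow band around the
#' fundamental movement frequency: the band has total width
#' `band_width_fraction * f0` centered on `f0` (default 10%, i.e.
#' f0 +/- 5%), and the denominator is the total non-DC power up to
#' Nyquist. The CPI is 1 for a pure sinusoid at `f0` and falls toward 0
#' as power spreads into harmonics and broadband noise.
#'
#' @param spectrum a `spectral_density` from [power_spectrum()].
#' @param f0 fundamental frequency, Hz; must lie within the spectrum
#'   support.
#' @param band_width_fraction total relative band width (default 0.10).
#' @return an object of class `cpi_result` with fields `cpi`, `f0`,
#'   `band` (the band actually used, Hz).
#' @export
coordination_pattern_index <- function(spectrum, f0,
                                       band_width_fraction = 0.10) {
  stopifnot(inherits(spectrum, "spectral_density"))
  if (!is.numeric(f0) || f0 <= 0 || f0 > max(spectrum$freqs))
    stop_parameter("f0 must be positive and within the spectrum support")
  w <- band_width_fraction
  band <- c(f0 * (1 - w / 2), f0 * (1 + w / 2))
  nz <- spectrum$freqs > 0
  in_band <- nz & spectrum$freqs >= band[1] & spectrum$freqs <= band[2]
  if (!any(in_band))
    stop_coordrqa(sprintf(
      "no spectral bin inside [%.4g, %.4g] Hz at resolution %.4g Hz; need a signal of at least %.0f samples",
      band[1], band[2], spectrum$resolution,
      ceiling(1 / (f0 * w) * spectrum$resolution *
                length(spectrum$freqs) * 2)),
      "coordrqa_resolution_error")
  total <- sum(spectrum$power[nz])
  if (total <= 0) stop_parameter("spectrum has no non-DC power")
  structure(list(cpi = sum(spectrum$power[in_band]) / total,
                 f0 = f0, band = band,
                 band_width_fraction = band_width_fraction),
            class = "cpi_result")
}

#' @export
print.cpi_result <- function(x, ...) {
  cat(sprintf("<cpi_result: CPI = %.4f at f0 = %.4g Hz (band %.4g-%.4g Hz)>\n",
              x$cpi, x$f0, x$band[1], x$band[2]))
  invisible(x)
}

#' Normalize a spectrum by the fundamental frequency
#'
#' Divides the frequency axis by `f0` so the fundamental maps to 1.0 and
#' harmonics to integers; power is unchanged.
#'
#' @param spectrum a `spectral_density`.
#' @param f0 fundamental frequency, Hz (> 0).
#' @return a `spectral_density` with dimensionless frequency axis.
#' @export
normalize_spectrum <- function(spectrum, f0) {
  stopifnot(inherits(spectrum, "spectral_density"))
  if (!is.numeric(f0) || f0 <= 0) stop_parameter("f0 must be > 0")
  structure(list(freqs = spectrum$freqs / f0, power = spectrum$power,
                 resolution = spectrum$resolution / f0),
            class = "spectral_density")
}

#' Participant-level CPI
#'
#' The representative CPI for a participant is the arithmetic mean of the
#' left- and right-hand values.
#'
#' @param left,right `cpi_result` objects or plain CPI values in
#'   `[0, 1]`.
#' @return the mean CPI, dimensionless.
#' @export
participant_cpi <- function(left, right) {
  v <- vapply(list(left, right), function(z) {
    if (inherits(z, "cpi_result")) z$cpi else as.numeric(z)
  }, numeric(1))
  if (any(v < 0 | v > 1)) stop_parameter("CPI values must lie in [0, 1]")
  mean(v)
}
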