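#' Uniformly sampled scalar signal
#'
#' Lightweight container for a uniformly sampled kinematic series: marker
#' position along one axis, vertical velocity, or the 3D head-wrist
#' distance. All preprocessing and spectral operations consume and return
#' this class.
#'
#' @param values numeric vector of samples (mm or mm/s). Must be finite and
#'   of length at least 2.
#' @param rate sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @param meaning free-text tag describing the quantity, e.g.
#'   `"position_SI"`, `"velocity_SI"`, `"distance_3D"`.
#' @return an object of class `sampled_signal`.
#' @examples
#' s <- sampled_signal(sin(2 * pi * 2 * (0:499) / 100), rate = 100)
#' signal_time(s)[1:3]
#' @export
sampled_signal <- function(values, rate, t0 = 0, meaning = "signal") {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop_parameter("a sampled_signal needs at least 2 samples")
  if (!all(is.finite(values)))
    stop_parameter("sampled_signal values must all be finite")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop_parameter("sampling rate must be a single positive number")
  structure(
    list(values = values, rate = as.numeric(rate), t0 = as.numeric(t0),
         meaning = as.character(meaning)),
    class = "sampled_signal"
  )
}

#' @export
length.sampled_signal <- function(x) length(x$values)

#' Sample times of a signal
#'
#' @param x a [sampled_signal()].
#' @return numeric vector of sample times in seconds.
#' @export
signal_time <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$t0 + (seq_along(x$values) - 1) / x$rate
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal: %s, %d samples @ %g Hz, t0 = %g s>\n",
              x$meaning, length(x$values), x$rate, x$t0))
  invisible(x)
}

as_signal_values <- function(x) {
  if (inherits(x, "sampled_signal")) x$values else as.numeric(x)
}
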