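# Kinematic preprocessing: thinning, residual-analysis cutoff selection,
# zero-phase Butterworth filtering, differentiation, head-wrist distance,
# cycle extraction and length standardization.

#' Downsample by thinning
#'
#' Literal decimation: keeps every `factor`-th sample starting at the
#' first, with no anti-alias filtering. Used to bring auxiliary streams
#' recorded at a higher rate (e.g. 1000 Hz audio sync) down to the
#' motion-capture rate.
#'
#' @param signal a [sampled_signal()].
#' @param factor positive integer decimation factor.
#' @return a [sampled_signal()] at `rate / factor`.
#' @export
downsample_thinning <- function(signal, factor) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (!is.numeric(factor) || factor < 1 || factor != round(factor))
    stop_parameter("factor must be a positive integer")
  factor <- as.integer(factor)
  idx <- seq(1L, length(signal$values), by = factor)
  sampled_signal(signal$values[idx], signal$rate / factor, signal$t0,
                 signal$meaning)
}

#' Low-pass cutoff by residual analysis
#'
#' Winter-style residual analysis: for each candidate cutoff the RMS
#' residual between the raw signal and its zero-phase second-order
#' Butterworth-filtered version is computed; a straight line is fitted to
#' the noise-dominated high-frequency tail of the residual curve and
#' extrapolated to 0 Hz. The selected cutoff is the smallest candidate
#' whose residual does not exceed that intercept (the point where signal
#' distortion balances noise passed).
#'
#' @param signal a [sampled_signal()].
#' @param candidate_cutoffs at least 5 candidate cutoffs in
#'   (0, Nyquist), Hz.
#' @param tail_fraction fraction of the candidate range (from the top)
#'   treated as the noise-dominated tail for the line fit.
#' @return selected cutoff frequency, Hz. For an (near-)noiseless signal
#'   the residual curve is flat or the intercept non-positive; the
#'   smallest candidate is returned with a warning.
#' @export
residual_cutoff <- function(signal, candidate_cutoffs = seq(2, 20, by = 1),
                            tail_fraction = 1 / 3) {
  stopifnot(inherits(signal, "sampled_signal"))
  fc <- sort(as.numeric(candidate_cutoffs))
  nyq <- signal$rate / 2
  if (length(fc) < 5) stop_parameter("need at least 5 candidate cutoffs")
  if (any(fc <= 0 | fc >= nyq))
    stop_parameter("candidate cutoffs must lie in (0, Nyquist)")
  x <- signal$values
  resid <- vapply(fc, function(f) {
    filt <- butterworth_filter(signal, cutoff = f)
    sqrt(mean((x - filt$values)^2))
  }, numeric(1))

  scale <- max(sqrt(mean(x^2)), .Machine$double.eps)
  if (diff(range(resid)) < 1e-12 * scale) {
    warning("flat residual curve (noiseless input); returning smallest candidate")
    return(fc[1])
  }
  tail_lo <- max(fc) - tail_fraction * diff(range(fc))
  in_tail <- fc >= tail_lo
  if (sum(in_tail) < 2) in_tail <- fc >= sort(fc, decreasing = TRUE)[2]
  fit <- stats::lm(resid[in_tail] ~ fc[in_tail])
  intercept <- unname(coef(fit)[1])
  if (intercept <= 1e-3 * scale) {
    # extrapolated noise floor is negligible next to the signal
    warning("residual analysis finds no appreciable noise; returning smallest candidate")
    return(fc[1])
  }
  ok <- which(resid <= intercept)
  if (length(ok) == 0) {
    warning("no candidate at or below the residual intercept; returning largest")
    return(fc[length(fc)])
  }
  fc[min(ok)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order Butterworth low-pass applied forward and backward
#' (`signal::filtfilt`), so the pass introduces no phase lag and event
#' timing is preserved. Attenuation at the cutoff is about -3 dB per
#' pass.
#'
#' @param signal a [sampled_signal()].
#' @param cutoff cutoff frequency, Hz; must be below Nyquist.
#' @param order filter order (default 2).
#' @param zero_phase apply forward-backward (default `TRUE`); otherwise a
#'   single causal pass.
#' @return filtered [sampled_signal()], same length and rate.
#' @export
butterworth_filter <- function(signal, cutoff, order = 2, zero_phase = TRUE) {
  stopifnot(inherits(signal, "sampled_signal"))
  nyq <- signal$rate / 2
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= nyq)
    stop_parameter("cutoff must lie in (0, Nyquist)")
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  x <- signal$values
  y <- if (zero_phase) {
    # odd-reflection padding suppresses the start/end transients of the
    # forward-backward pass (the filter starts from zero state)
    n <- length(x)
    np <- min(n - 1, max(48, ceiling(3 * signal$rate / cutoff)))
    xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
    yp <- signal::filtfilt(bf, xp)
    yp[(np + 1):(np + n)]
  } else {
    as.numeric(signal::filter(bf, x))
  }
  sampled_signal(y, signal$rate, signal$t0, signal$meaning)
}

#' Differentiate a signal
#'
#' Central differences in the interior, one-sided differences at the
#' ends. Units mm become mm/s; length is preserved.
#'
#' @param signal a [sampled_signal()] of positions.
#' @return a [sampled_signal()] of velocities.
#' @export
differentiate <- function(signal) {
  stopifnot(inherits(signal, "sampled_signal"))
  x <- signal$values
  n <- length(x)
  if (n < 3) stop_parameter("need at least 3 samples to differentiate")
  dt <- 1 / signal$rate
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  sampled_signal(v, signal$rate, signal$t0,
                 paste0("velocity_", sub("^position_", "", signal$meaning)))
}

#' 3D head-wrist distance
#'
#' Per-frame Euclidean distance between the head-vertex marker and a
#' wrist marker.
#'
#' @param head,wrist N x 3 matrices of marker positions, mm (columns
#'   x, y, z), equal length.
#' @param rate sampling rate, Hz.
#' @param t0 time of first sample, s.
#' @return a [sampled_signal()] tagged `distance_3D`, mm.
#' @export
head_wrist_distance <- function(head, wrist, rate = 100, t0 = 0) {
  head <- as.matrix(head); wrist <- as.matrix(wrist)
  if (!all(dim(head) == dim(wrist)) || ncol(head) != 3)
    stop_coordrqa("head and wrist must be N x 3 matrices of equal size",
                  "coordrqa_shape_error")
  d <- sqrt(rowSums((head - wrist)^2))
  sampled_signal(d, rate, t0, "distance_3D")
}

#' Resample a signal to a fixed number of points
#'
#' Linear-interpolation resampling onto `n_points` equally spaced times
#' spanning the original support; the endpoints are preserved exactly.
#' Used to standardize every 25-cycle segment to 2500 points before
#' embedding, so that recurrence structure is compared on a common grid
#' (100 points per cycle).
#'
#' @param signal a [sampled_signal()].
#' @param n_points target length (default 2500).
#' @return a [sampled_signal()] of length `n_points`; its `rate` is the
#'   implied rate `(n_points - 1) / span`.
#' @export
standardize_length <- function(signal, n_points = 2500) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (!is.numeric(n_points) || n_points < 2)
    stop_parameter("n_points must be >= 2")
  n_points <- as.integer(n_points)
  t_old <- signal_time(signal)
  t_new <- seq(t_old[1], t_old[length(t_old)], length.out = n_points)
  y <- approx(t_old, signal$values, xout = t_new)$y
  span <- t_new[n_points] - t_new[1]
  sampled_signal(y, (n_points - 1) / span, signal$t0, signal$meaning)
}

#' Extract a fixed number of movement cycles
#'
#' Cuts the segment of `signal` spanning `n_cycles` complete same-hand
#' catch-to-catch cycles, after skipping `skip` warm-up cycles at the
#' start.
#'
#' @param signal a [sampled_signal()].
#' @param catch_times one hand's catch times, seconds, strictly
#'   increasing (see [hand_catches()]).
#' @param n_cycles number of cycles to keep (default 25).
#' @param skip warm-up cycles to discard first (default 2).
#' @return the [sampled_signal()] segment from the start of cycle
#'   `skip + 1` to the end of cycle `skip + n_cycles`.
#' @export
extract_cycles <- function(signal, catch_times, n_cycles = 25, skip = 2) {
  stopifnot(inherits(signal, "sampled_signal"))
  t <- signal_time(signal)
  ct <- catch_times[catch_times >= t[1] & catch_times <= t[length(t)]]
  avail <- length(ct) - 1L # complete catch-to-catch cycles in support
  if (avail < skip + n_cycles)
    stop_insufficient(sprintf(
      "need %d same-hand cycles (%d analysis + %d warm-up) but only %d available",
      skip + n_cycles, n_cycles, skip, max(avail, 0)),
      n_found = max(avail, 0), n_required = skip + n_cycles)
  t_start <- ct[skip + 1L]
  t_end <- ct[skip + 1L + n_cycles]
  i0 <- which.min(abs(t - t_start))
  i1 <- which.min(abs(t - t_end))
  sampled_signal(signal$values[i0:i1], signal$rate, t[i0], signal$meaning)
}
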