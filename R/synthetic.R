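# Synthetic juggling-like kinematics: metronome trains, hand-cycle
# waveforms on a rhythmic-to-discrete continuum, full trials and cohorts.

#' Movement pattern parameters
#'
#' Describes one hand's cyclical movement on the rhythmic-to-discrete
#' continuum. `dwell_fraction = 0` gives a pure sinusoidal (rhythmic)
#' pattern; larger values compress the up-down excursion into the first
#' part of the cycle and hold the hand motionless (at the rest position)
#' for the remainder, emulating a discrete move-and-dwell pattern.
#'
#' @param cycle_duration seconds per full hand cycle (> 0). For
#'   metronome-paced cascade juggling with alternating hands this is twice
#'   the beep interval.
#' @param dwell_fraction fraction of the cycle spent motionless, in
#'   `[0, 0.9]`.
#' @param amplitude vertical excursion in mm (> 0); the waveform's
#'   peak-to-peak range is `2 * amplitude` for every dwell fraction.
#' @param noise_sd standard deviation of additive Gaussian measurement
#'   noise, mm (>= 0).
#' @param phase_offset phase between left and right hands in radians.
#'   With one catch per beep and alternating hands the natural offset is
#'   `pi`; other values shift the left hand's waveform relative to its
#'   catch anchor.
#' @param seed optional integer RNG seed stored with the parameters.
#' @return an object of class `pattern_params`.
#' @export
pattern_params <- function(cycle_duration, dwell_fraction = 0,
                           amplitude = 100, noise_sd = 2,
                           phase_offset = pi, seed = NULL) {
  if (!is.numeric(cycle_duration) || cycle_duration <= 0)
    stop_parameter("cycle_duration must be > 0")
  if (!is.numeric(dwell_fraction) || dwell_fraction < 0 || dwell_fraction >= 1)
    stop_parameter("dwell_fraction must lie in [0, 1)")
  if (dwell_fraction > 0.9)
    stop_parameter("dwell_fraction above 0.9 leaves too little movement time")
  if (!is.numeric(amplitude) || amplitude <= 0)
    stop_parameter("amplitude must be > 0")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_parameter("noise_sd must be >= 0")
  structure(
    list(cycle_duration = cycle_duration, dwell_fraction = dwell_fraction,
         amplitude = amplitude, noise_sd = noise_sd,
         phase_offset = phase_offset, seed = seed),
    class = "pattern_params"
  )
}

#' Metronome beep train
#'
#' Builds the beep-onset schedules used by the pacing task: a fixed-tempo
#' train of 65 beeps, a 101-beep ramp whose inter-beep interval shrinks
#' from 600 ms in 3 ms steps (`up_ramp`, tempo speeding up), its exact
#' reverse (`down_ramp`), or no metronome at all (`none`, the free-tempo
#' condition).
#'
#' With 101 beeps a ramp realizes 100 intervals; the up ramp realizes
#' 600, 597, ..., 303 ms, so the nominal 300 ms endpoint is never an
#' actual inter-beep interval. The chosen convention is recorded in the
#' returned object's `note` field.
#'
#' @param condition one of `"fixed"`, `"up_ramp"`, `"down_ramp"`,
#'   `"none"`.
#' @param interval_ms beep interval in ms for `fixed` (must lie in
#'   `[100, 2000]`).
#' @param n_beeps number of beeps for `fixed` trains (default 65).
#' @param step_ms ramp step in ms (default 3).
#' @param ramp_from_ms,ramp_to_ms nominal ramp endpoints in ms
#'   (default 600 down to 300).
#' @param duration_s trial duration for `none` (free-tempo) trains,
#'   seconds (default 30).
#' @return an object of class `beep_train` with fields `onsets` (s),
#'   `intervals` (ms), `condition`.
#' @examples
#' tr <- make_beep_train("fixed", interval_ms = 500)
#' length(tr$onsets)  # 65
#' up <- make_beep_train("up_ramp")
#' head(up$intervals)  # 600 597 594 ...
#' @export
make_beep_train <- function(condition = c("fixed", "up_ramp", "down_ramp", "none"),
                            interval_ms = NULL, n_beeps = 65, step_ms = 3,
                            ramp_from_ms = 600, ramp_to_ms = 300,
                            duration_s = 30) {
  condition <- match.arg(condition)
  if (condition == "fixed") {
    if (is.null(interval_ms) || !is.numeric(interval_ms) || interval_ms <= 0)
      stop_parameter("fixed trains need a positive interval_ms")
    if (interval_ms < 100 || interval_ms > 2000)
      stop_parameter("fixed interval_ms must lie in [100, 2000] ms")
    if (n_beeps < 2) stop_parameter("n_beeps must be >= 2")
    intervals <- rep(interval_ms, n_beeps - 1L)
    note <- NULL
  } else if (condition %in% c("up_ramp", "down_ramp")) {
    if (step_ms <= 0) stop_parameter("ramp step_ms must be > 0")
    if (ramp_from_ms <= 0 || ramp_to_ms <= 0)
      stop_parameter("ramp endpoints must be positive")
    n_int <- round((ramp_from_ms - ramp_to_ms) / step_ms)
    up <- ramp_from_ms - step_ms * (seq_len(n_int) - 1L)
    intervals <- if (condition == "up_ramp") up else rev(up)
    note <- sprintf(
      "ramp realizes intervals %g..%g ms; nominal endpoint %g ms is not an inter-beep interval",
      intervals[1], intervals[length(intervals)], ramp_to_ms)
  } else { # none
    return(structure(
      list(onsets = numeric(0), intervals = numeric(0), condition = "none",
           duration_s = duration_s, note = "free tempo, no metronome"),
      class = "beep_train"
    ))
  }
  onsets <- cumsum(c(0, intervals)) / 1000
  structure(
    list(onsets = onsets, intervals = intervals, condition = condition,
         interval_ms = if (condition == "fixed") interval_ms else NULL,
         note = note),
    class = "beep_train"
  )
}

#' @export
print.beep_train <- function(x, ...) {
  cat(sprintf("<beep_train: %s, %d onsets>\n", x$condition, length(x$onsets)))
  invisible(x)
}

#' Hand-cycle waveform
#'
#' Vertical wrist position (mm, relative to the rest position) at time
#' `t_in_cycle` within one movement cycle. With `dwell_fraction = 0` the
#' waveform is a pure sinusoid of period `cycle_duration`. With
#' `dwell_fraction = d > 0` the up-down excursion is compressed into the
#' first `(1 - d) * cycle_duration` as a pair of raised-cosine bumps
#' (up to `+amplitude`, down to `-amplitude`), followed by a dwell at the
#' rest position; velocity vanishes at every junction, so the waveform is
#' continuously differentiable.
#'
#' @param pattern a [pattern_params()].
#' @param t_in_cycle time(s) within the cycle, `0 <= t < cycle_duration`.
#'   Vectorized.
#' @param cycle_duration optional override of the pattern's nominal cycle
#'   duration (used when a cycle is stretched to land on observed catch
#'   times).
#' @return numeric vector of positions, mm.
#' @examples
#' p <- pattern_params(cycle_duration = 1, amplitude = 100)
#' simulate_hand_cycle(p, 0.25)  # sine peak: +100
#' pd <- pattern_params(1, dwell_fraction = 0.5)
#' simulate_hand_cycle(pd, 0.75)  # inside the dwell: 0
#' @export
simulate_hand_cycle <- function(pattern, t_in_cycle,
                                cycle_duration = pattern$cycle_duration) {
  stopifnot(inherits(pattern, "pattern_params"))
  t <- as.numeric(t_in_cycle)
  if (any(t < 0 | t >= cycle_duration))
    stop_parameter("t_in_cycle must satisfy 0 <= t < cycle_duration")
  d <- pattern$dwell_fraction
  A <- pattern$amplitude
  if (d == 0) return(A * sin(2 * pi * t / cycle_duration))
  t_active <- (1 - d) * cycle_duration
  u <- t / t_active
  y <- numeric(length(t))
  act <- u < 1
  bump <- A * (1 - cos(4 * pi * u[act])) / 2
  y[act] <- ifelse(u[act] < 0.5, bump, -bump)
  y
}

# Render one hand's wrist trajectory: each inter-catch interval is one
# cycle anchored at the catches. For d = 0 the whole sinusoid rescales
# to the realized interval (oscillator-like entrainment). For d > 0 the
# cycle is a waiting period followed by the up-down movement that ends
# at the next catch; the wait is terminated by an internally timed
# trigger whose variability follows the scalar (Weber) property of
# interval timing, sd = weber_fraction * nominal dwell duration. This
# event-dependent re-initiation is what progressively degrades the
# trajectory's cycle-to-cycle alignment as patterns become more
# discrete.
render_hand_track <- function(pattern, t, catches, phase_shift = 0,
                              weber_fraction = 0.15) {
  d <- pattern$dwell_fraction
  T_nom <- pattern$cycle_duration
  y <- numeric(length(t))
  # extend one virtual cycle before the first catch so the track starts moving
  bounds <- c(catches[1] - T_nom, catches)
  n_cyc <- length(bounds) - 1L
  k <- findInterval(t, bounds)
  inside <- k >= 1L & k < length(bounds)
  kk <- k[inside]
  tloc <- t[inside] - bounds[kk]
  dur_all <- diff(bounds)
  dur <- dur_all[kk]
  if (phase_shift != 0) tloc <- (tloc + phase_shift * dur / (2 * pi)) %% dur
  A <- pattern$amplitude
  if (d == 0) {
    y[inside] <- A * sin(2 * pi * tloc / dur)
  } else {
    dwell_nom <- d * T_nom
    dwell_cyc <- dwell_nom + weber_fraction * dwell_nom * rnorm(n_cyc)
    # the movement keeps at least a quarter of its nominal duration
    dwell_cyc <- pmin(pmax(dwell_cyc, 0),
                      dur_all - 0.25 * (1 - d) * T_nom)
    dw <- dwell_cyc[kk]
    u <- (tloc - dw) / (dur - dw)
    act <- u >= 0 & u < 1
    yy <- numeric(length(u))
    bump <- A * (1 - cos(4 * pi * u[act])) / 2
    yy[act] <- ifelse(u[act] < 0.5, bump, -bump)
    y[inside] <- yy
  }
  y
}

#' Simulate one juggling-like trial
#'
#' Generates a full trial: catch events anchored to (or, in the
#' free-tempo condition, self-paced around) the beep train, and 3D marker
#' trajectories for head vertex and both wrists sampled at `rate` Hz.
#' Catches alternate hands, left hand first, one catch per beep; the
#' k-th catch time is the k-th beep onset plus a Gaussian lag
#' `N(lag_mean, lag_sd)`. Each hand's vertical wrist movement is the
#' cycle waveform re-timed so cycle boundaries land on that hand's catch
#' times; anteroposterior and mediolateral components are scaled-down
#' copies of the vertical waveform (hands move mostly vertically). The
#' head marker is stationary plus noise.
#'
#' Axis convention: column `x` = anteroposterior, `y` = superoinferior
#' (vertical), `z` = mediolateral.
#'
#' @param pattern a [pattern_params()].
#' @param beeps a [make_beep_train()] result. For `condition = "none"`
#'   catches are self-paced: merged-hand catches are spaced half a cycle
#'   apart with timing noise `lag_sd` accumulating from catch to catch.
#' @param lag_mean,lag_sd mean and sd (seconds) of the per-catch timing
#'   error. `lag_sd < 0` is an error.
#' @param seed integer seed; identical arguments and seed give
#'   bit-identical trials.
#' @param rate sampling rate, Hz.
#' @return an object of class `trial_bundle` with fields `head`,
#'   `wrist_left`, `wrist_right` (N x 3 matrices, mm), `beeps`, `events`,
#'   `rate`, `condition`, `time`.
#' @export
simulate_trial <- function(pattern, beeps, lag_mean = 0, lag_sd = 0,
                           seed = NULL, rate = 100) {
  stopifnot(inherits(pattern, "pattern_params"), inherits(beeps, "beep_train"))
  if (!is.numeric(lag_sd) || lag_sd < 0)
    stop_parameter("lag_sd must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (beeps$condition == "none") {
    dur <- beeps$duration_s
    half <- pattern$cycle_duration / 2
    catches <- numeric(0)
    t_catch <- half / 2
    while (t_catch <= dur - half) {
      catches <- c(catches, t_catch)
      step <- half + rnorm(1, lag_mean, lag_sd)
      t_catch <- t_catch + max(step, 0.2 * half)
    }
    total_dur <- dur
  } else {
    lags <- rnorm(length(beeps$onsets), lag_mean, lag_sd)
    catches <- beeps$onsets + lags
    # keep the merged sequence strictly increasing (large lags only)
    catches <- cummax_strict(catches, eps = 1e-6)
    last_int <- if (length(beeps$intervals)) tail(beeps$intervals, 1) / 1000 else 0.5
    total_dur <- max(catches) + 1.5 * max(pattern$cycle_duration, 2 * last_int)
  }
  if (length(catches) < 2)
    stop_insufficient("trial produced fewer than 2 catches")

  hands <- rep(c("left", "right"), length.out = length(catches))
  events <- event_series(catch_times = catches, hands = hands)

  n <- ceiling(total_dur * rate) + 1L
  t <- (seq_len(n) - 1L) / rate
  extra_phase <- pattern$phase_offset - pi

  yL <- render_hand_track(pattern, t, catches[hands == "left"],
                          phase_shift = extra_phase)
  yR <- render_hand_track(pattern, t, catches[hands == "right"])

  mk_wrist <- function(y, base) {
    cbind(x = base[1] + 0.30 * y + rnorm(n, 0, pattern$noise_sd),
          y = base[2] + y + rnorm(n, 0, pattern$noise_sd),
          z = base[3] + 0.20 * y + rnorm(n, 0, pattern$noise_sd))
  }
  wrist_left <- mk_wrist(yL, c(50, 1000, -250))
  wrist_right <- mk_wrist(yR, c(50, 1000, 250))
  head <- cbind(x = rnorm(n, 0, pattern$noise_sd),
                y = 1700 + rnorm(n, 0, pattern$noise_sd),
                z = rnorm(n, 0, pattern$noise_sd))

  structure(
    list(head = head, wrist_left = wrist_left, wrist_right = wrist_right,
         beeps = beeps, events = events, rate = rate,
         condition = beeps$condition, pattern = pattern, time = t),
    class = "trial_bundle"
  )
}

cummax_strict <- function(x, eps = 1e-6) {
  for (i in seq_along(x)[-1])
    if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + eps
  x
}

#' Catch/throw event series
#'
#' @param catch_times strictly increasing catch times, seconds (merged
#'   across hands).
#' @param hands character vector of `"left"`/`"right"` labels, same
#'   length; catches must alternate hands in merged order.
#' @param throw_times,throw_hands optional throw events.
#' @return an object of class `event_series`.
#' @export
event_series <- function(catch_times, hands, throw_times = numeric(0),
                         throw_hands = character(0)) {
  if (length(catch_times) != length(hands))
    stop_parameter("catch_times and hands must have equal length")
  if (any(diff(catch_times) <= 0))
    stop_parameter("catch_times must be strictly increasing")
  if (!all(hands %in% c("left", "right")))
    stop_parameter("hands must be 'left' or 'right'")
  if (length(hands) > 1 && any(hands[-1] == hands[-length(hands)]))
    stop_parameter("catches must alternate between hands")
  structure(
    list(catch_times = catch_times, hands = hands,
         throw_times = throw_times, throw_hands = throw_hands),
    class = "event_series"
  )
}

#' Per-hand catch times
#'
#' @param events an [event_series()].
#' @param hand `"left"` or `"right"`.
#' @return numeric vector of catch times for that hand, seconds.
#' @export
hand_catches <- function(events, hand) {
  stopifnot(inherits(events, "event_series"))
  events$catch_times[events$hands == hand]
}

#' Simulate a cohort of participants
#'
#' Emulates a study cohort of intermediate jugglers: participant `i` has
#' an intrinsic dwell fraction `d_values[i]` (their position on the
#' rhythmic-to-discrete continuum), a preferred cycle duration drawn
#' uniformly from `preferred_range`, and performs `n_trials` trials in
#' each of three conditions: free-tempo `preferred` (30 s, no
#' metronome), `up_ramp`, and `down_ramp`.
#'
#' In the ramp conditions the per-catch timing-error sd is
#' `sigma0 + adaptability_coupling * (1 - d)`: more rhythmic (low-dwell)
#' participants track a changing tempo less accurately, encoding the
#' empirical finding that rhythmic coordination patterns adapt worse to
#' new timing constraints. With `adaptability_coupling = 0` every
#' participant shares the same lag distribution.
#'
#' @param n_participants number of participants (>= 2).
#' @param d_values dwell fractions, length `n_participants`.
#' @param adaptability_coupling coupling `c >= 0`, seconds of extra
#'   timing-error sd per unit of (1 - dwell fraction).
#' @param seed integer seed for the whole cohort.
#' @param n_trials trials per condition (default 3).
#' @param sigma0 baseline ramp timing-error sd, s.
#' @param lag_mean mean catch lag behind the beep, s.
#' @param sigma_pref self-paced timing-error sd in the free-tempo
#'   condition, s.
#' @param preferred_range range (s) of preferred cycle durations.
#' @param amplitude,noise_sd passed to [pattern_params()].
#' @param rate sampling rate, Hz.
#' @return list of participants; each has `id`, `dwell_fraction`,
#'   `preferred_cycle`, and `trials`, a named list with elements
#'   `preferred`, `up_ramp`, `down_ramp`, each a list of `trial_bundle`s.
#' @export
simulate_cohort <- function(n_participants = 10,
                            d_values = seq(0, 0.6, length.out = n_participants),
                            adaptability_coupling = 0.04,
                            seed = 1, n_trials = 3,
                            sigma0 = 0.010, lag_mean = 0.010,
                            sigma_pref = 0.020,
                            preferred_range = c(0.7, 1.0),
                            amplitude = 100, noise_sd = 2, rate = 100) {
  if (n_participants < 2) stop_parameter("n_participants must be >= 2")
  if (length(d_values) != n_participants)
    stop_parameter("d_values must have length n_participants")
  if (adaptability_coupling < 0)
    stop_parameter("adaptability_coupling must be >= 0")
  set.seed(as.integer(seed))
  part_seeds <- sample.int(.Machine$integer.max, n_participants)
  lapply(seq_len(n_participants), function(i) {
    set.seed(part_seeds[i])
    pref_cycle <- runif(1, preferred_range[1], preferred_range[2])
    d <- d_values[i]
    sigma_ramp <- sigma0 + adaptability_coupling * (1 - d)
    trial_seeds <- sample.int(.Machine$integer.max, 3 * n_trials)
    mk <- function(cond, j) {
      if (cond == "preferred") {
        pat <- pattern_params(pref_cycle, d, amplitude, noise_sd)
        beeps <- make_beep_train("none", duration_s = 30)
        simulate_trial(pat, beeps, lag_mean = 0, lag_sd = sigma_pref,
                       seed = trial_seeds[j], rate = rate)
      } else {
        beeps <- make_beep_train(cond)
        # nominal hand cycle = twice the mid-ramp interval
        pat <- pattern_params(2 * mean(beeps$intervals) / 1000, d,
                              amplitude, noise_sd)
        simulate_trial(pat, beeps, lag_mean = lag_mean, lag_sd = sigma_ramp,
                       seed = trial_seeds[j], rate = rate)
      }
    }
    trials <- list(
      preferred = lapply(seq_len(n_trials), function(j) mk("preferred", j)),
      up_ramp = lapply(seq_len(n_trials), function(j) mk("up_ramp", n_trials + j)),
      down_ramp = lapply(seq_len(n_trials), function(j) mk("down_ramp", 2 * n_trials + j))
    )
    list(id = i, dwell_fraction = d, preferred_cycle = pref_cycle,
         sigma_ramp = sigma_ramp, trials = trials)
  })
}
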