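# End-to-end orchestration: per-trial analysis (filter -> cycles ->
# standardize -> embed -> RQA, plus spectral CPI), the two experiment
# designs, cohort summaries, and plain-text trial I/O.

#' Default analysis parameters
#'
#' One place for every knob of the analysis chain, with the defaults
#' used throughout: 25 analysis cycles per hand after a 2-cycle warm-up,
#' standardization to 2500 points, delay 25 frames, dimension 6, radius
#' 15% of the maximum distance, Theiler window and minimum line length
#' 10, CPI band width 10% of the fundamental, 6 warm-up catches
#' discarded from %Asynchrony.
#'
#' @param ... overrides for any default listed above, by name.
#' @return named list of parameters.
#' @export
analysis_params <- function(...) {
  p <- list(
    channels = c("distance_3D", "ML", "SI", "AP"),
    n_cycles = 25, skip_cycles = 2, n_points = 2500,
    cutoff = 10, filter_order = 2,
    tau = 25, m = 6,
    radius_fraction = 0.15, theiler = 10, min_line = 10,
    band_width_fraction = 0.10,
    f0_convention = "half_beep_rate",
    preferred_f0 = "event_rate",
    discard_first = 6, pairing = "sequential", interval_side = "preceding"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop_parameter(paste("unknown analysis parameter(s):",
                         paste(unknown, collapse = ", ")))
  p[names(dots)] <- dots
  p
}

channel_signal <- function(trial, channel, hand) {
  wrist <- trial[[paste0("wrist_", hand)]]
  switch(channel,
         SI = sampled_signal(wrist[, "y"], trial$rate, 0,
                             "position_SI"),
         ML = sampled_signal(wrist[, "z"], trial$rate, 0, "position_ML"),
         AP = sampled_signal(wrist[, "x"], trial$rate, 0, "position_AP"),
         distance_3D = head_wrist_distance(trial$head, wrist, trial$rate),
         stop_parameter(paste("unknown channel:", channel)))
}

#' Analyze a single trial
#'
#' Runs the full chain on one trial: for each hand, the vertical wrist
#' position is low-pass filtered and differentiated to velocity, the
#' 25-cycle analysis window is cut at that hand's catch times, and the
#' CPI is computed from the velocity periodogram (fundamental from the
#' metronome for fixed-tempo trials, by peak picking otherwise). For
#' each requested channel the filtered position (or 3D head-wrist
#' distance) over the same window is standardized to `n_points`,
#' delay-embedded, and quantified with RQA. Hand values are averaged
#' into participant-level representatives.
#'
#' @param trial a `trial_bundle` from [simulate_trial()] or
#'   [read_trial()].
#' @param params an [analysis_params()] list. Set `cutoff = "residual"`
#'   to pick the filter cutoff by residual analysis per hand.
#' @return list with `cpi` (hand mean), `cpi_hand` (named numeric),
#'   `f0_hand`, `rqa` (named list of `rqa_metrics`, one per channel,
#'   hand-averaged), `rqa_hand` (nested list channel -> hand).
#' @export
analyze_trial <- function(trial, params = analysis_params()) {
  stopifnot(inherits(trial, "trial_bundle"))
  hands <- c("left", "right")
  cpi_hand <- numeric(0)
  f0_hand <- numeric(0)
  rqa_hand <- list()
  for (hand in hands) {
    catches <- hand_catches(trial$events, hand)
    si_raw <- channel_signal(trial, "SI", hand)
    cutoff <- params$cutoff
    if (identical(cutoff, "residual")) cutoff <- residual_cutoff(si_raw)
    si <- butterworth_filter(si_raw, cutoff, params$filter_order)
    vel <- differentiate(si)
    vel_seg <- extract_cycles(vel, catches, params$n_cycles,
                              params$skip_cycles)
    spec <- power_spectrum(vel_seg)
    f0 <- if (trial$beeps$condition == "fixed") {
      fundamental_frequency(trial$beeps, convention = params$f0_convention)
    } else if (identical(params$preferred_f0, "event_rate")) {
      # the catch events define the movement cycle: mean same-hand
      # catch-to-catch duration over the analyzed cycles (peak picking
      # can mistake a harmonic for the fundamental in discrete patterns)
      ct <- catches[catches >= vel_seg$t0 - 1e-9 &
                      catches <= vel_seg$t0 +
                      (length(vel_seg) - 1) / vel_seg$rate + 1e-9]
      (length(ct) - 1) / (ct[length(ct)] - ct[1])
    } else {
      fundamental_frequency(signal = vel_seg)
    }
    cpi <- coordination_pattern_index(spec, f0, params$band_width_fraction)
    cpi_hand[hand] <- cpi$cpi
    f0_hand[hand] <- f0
    for (channel in params$channels) {
      sig <- if (channel == "SI") si else {
        butterworth_filter(channel_signal(trial, channel, hand), cutoff,
                           params$filter_order)
      }
      seg <- extract_cycles(sig, catches, params$n_cycles,
                            params$skip_cycles)
      std <- standardize_length(seg, params$n_points)
      att <- delay_embed(std, params$tau, params$m)
      rqa_hand[[channel]][[hand]] <-
        rqa_analyze(att, params$radius_fraction, params$theiler,
                    params$min_line)
    }
  }
  rqa <- lapply(rqa_hand, function(h) participant_rqa(h$left, h$right))
  list(cpi = mean(cpi_hand), cpi_hand = cpi_hand, f0_hand = f0_hand,
       rqa = rqa, rqa_hand = rqa_hand)
}

#' Score a ramped trial's synchronization performance
#'
#' @param trial a ramped-tempo `trial_bundle`.
#' @param params an [analysis_params()] list.
#' @return `percent_asynchrony` scalar for the trial.
#' @export
trial_asynchrony <- function(trial, params = analysis_params()) {
  pairs <- pair_catches_to_beeps(trial$events, trial$beeps, params$pairing)
  res <- percent_asynchrony(pairs, trial$beeps, params$discard_first,
                            params$interval_side)
  res$percent_asynchrony
}

#' Summarize a simulated cohort
#'
#' Per participant: CPI in the free-tempo condition, hand-averaged RQA
#' indices per channel (both averaged over the available trials), and
#' mean %Asynchrony in the up and down ramp conditions. A failing trial
#' is logged and skipped rather than aborting the cohort.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param params an [analysis_params()] list.
#' @return data.frame with one row per participant: `participant`,
#'   `dwell_fraction`, `cpi`, then `rec_`/`det_`/`maxline_` columns per
#'   channel, `asyn_up`, `asyn_down`.
#' @export
cohort_summary <- function(cohort, params = analysis_params()) {
  rows <- lapply(cohort, function(p) {
    res <- lapply(p$trials$preferred, function(tr) {
      tryCatch(analyze_trial(tr, params),
               error = function(e) {
                 message(sprintf("participant %d preferred trial failed: %s",
                                 p$id, conditionMessage(e)))
                 NULL
               })
    })
    res <- Filter(Negate(is.null), res)
    row <- list(participant = p$id, dwell_fraction = p$dwell_fraction)
    if (length(res) > 0) {
      row$cpi <- mean(vapply(res, `[[`, numeric(1), "cpi"))
      for (ch in params$channels) {
        row[[paste0("rec_", ch)]] <-
          mean(vapply(res, function(r) r$rqa[[ch]]$rec, numeric(1)))
        row[[paste0("det_", ch)]] <-
          mean(vapply(res, function(r) r$rqa[[ch]]$det, numeric(1)))
        row[[paste0("maxline_", ch)]] <-
          mean(vapply(res, function(r) r$rqa[[ch]]$maxline, numeric(1)))
      }
    } else {
      row$cpi <- NA_real_
      for (ch in params$channels)
        row[paste0(c("rec_", "det_", "maxline_"), ch)] <- NA_real_
    }
    for (cond in c("up_ramp", "down_ramp")) {
      v <- vapply(p$trials[[cond]], function(tr) {
        tryCatch(trial_asynchrony(tr, params),
                 error = function(e) NA_real_)
      }, numeric(1))
      row[[if (cond == "up_ramp") "asyn_up" else "asyn_down"]] <-
        mean(v, na.rm = TRUE)
    }
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

rqa_index_correlations <- function(summary_df, xvar, channels, method,
                                   label) {
  idx <- expand.grid(index = c("rec", "det", "maxline"),
                     channel = channels, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(idx)), function(i) {
    col <- paste0(idx$index[i], "_", idx$channel[i])
    ct <- tryCatch(correlation_test(summary_df[[xvar]], summary_df[[col]],
                                    method),
                   error = function(e) NULL)
    data.frame(analysis = label, index = idx$index[i],
               channel = idx$channel[i],
               method = if (is.null(ct)) NA_character_ else ct$method,
               n = if (is.null(ct)) NA_integer_ else ct$n,
               r = if (is.null(ct)) NA_real_ else ct$r,
               p = if (is.null(ct)) NA_real_ else ct$p)
  })
  do.call(rbind, rows)
}

#' Experiment 1: stability across tempo-induced coordination patterns
#'
#' Simulates expert jugglers performing fixed-tempo trials at the ten
#' metronome intervals 260-620 ms. Faster tempos induce rhythmic
#' (low-dwell) patterns and slower tempos discrete ones, with an
#' expert-specific ceiling on how discrete the pattern becomes. For each
#' participant x tempo cell the CPI and the RQA indices of the four
#' channels are computed; the result includes Pearson correlations of
#' CPI with tempo and with each RQA index per channel (12 analyses,
#' Bonferroni k = 12), plus per-participant Fisher-z summaries.
#'
#' @param n_participants number of experts (default 7).
#' @param tempos_ms metronome intervals, ms.
#' @param dmax_range range of each expert's maximum dwell fraction
#'   (reached at the slowest tempo).
#' @param lag_sd per-catch timing-error sd, s.
#' @param seed integer seed.
#' @param params an [analysis_params()] list.
#' @return list of tables: `cpi_table` (one row per participant x
#'   tempo), `rqa_table` (per participant x tempo x channel),
#'   `cpi_tempo` (correlation + Fisher summary), `cpi_rqa` (12
#'   correlation rows), `alpha` (Bonferroni-corrected level and printed
#'   form), `manifest`.
#' @export
run_experiment1 <- function(n_participants = 7,
                            tempos_ms = seq(260, 620, by = 40),
                            dmax_range = c(0.35, 0.65),
                            lag_sd = 0.015, seed = 1,
                            params = analysis_params()) {
  set.seed(as.integer(seed))
  dmax <- runif(n_participants, dmax_range[1], dmax_range[2])
  trial_seeds <- matrix(
    sample.int(.Machine$integer.max, n_participants * length(tempos_ms)),
    n_participants)
  cpi_rows <- list(); rqa_rows <- list()
  for (i in seq_len(n_participants)) {
    for (j in seq_along(tempos_ms)) {
      interval <- tempos_ms[j]
      d <- dmax[i] * (interval - min(tempos_ms)) /
        (max(tempos_ms) - min(tempos_ms))
      cell <- tryCatch({
        beeps <- make_beep_train("fixed", interval_ms = interval)
        pat <- pattern_params(2 * interval / 1000, d)
        trial <- simulate_trial(pat, beeps, lag_mean = 0.01,
                                lag_sd = lag_sd, seed = trial_seeds[i, j])
        analyze_trial(trial, params)
      }, error = function(e) {
        message(sprintf("participant %d, %d ms failed: %s", i, interval,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(cell)) next
      cpi_rows[[length(cpi_rows) + 1L]] <-
        data.frame(participant = i, interval_ms = interval, cpi = cell$cpi)
      for (ch in params$channels)
        rqa_rows[[length(rqa_rows) + 1L]] <- data.frame(
          participant = i, interval_ms = interval, channel = ch,
          rec = cell$rqa[[ch]]$rec, det = cell$rqa[[ch]]$det,
          maxline = cell$rqa[[ch]]$maxline)
    }
  }
  cpi_table <- do.call(rbind, cpi_rows)
  rqa_table <- do.call(rbind, rqa_rows)

  # CPI vs tempo, pooled plus per-participant Fisher-z summary
  ct <- correlation_test(cpi_table$interval_ms, cpi_table$cpi, "pearson")
  per_r <- vapply(split(cpi_table, cpi_table$participant), function(df) {
    correlation_test(df$interval_ms, df$cpi, "pearson")$r
  }, numeric(1))
  cpi_tempo <- c(ct, fisher_summary(per_r))

  # CPI vs each RQA index per channel
  wide <- merge(cpi_table, stats::reshape(
    rqa_table, direction = "wide", idvar = c("participant", "interval_ms"),
    timevar = "channel"), by = c("participant", "interval_ms"))
  names(wide) <- sub("^(rec|det|maxline)\\.", "\\1_", names(wide))
  cpi_rqa <- rqa_index_correlations(wide, "cpi", params$channels,
                                    "pearson", "cpi_vs_rqa")
  alpha12 <- bonferroni_alpha(0.05, 12)
  list(cpi_table = cpi_table, rqa_table = rqa_table,
       cpi_tempo = cpi_tempo, cpi_rqa = cpi_rqa,
       alpha = list(level = alpha12,
                    printed = format_alpha_percent(alpha12), k = 12),
       manifest = run_manifest("exp1", seed,
                               list(n_participants = n_participants,
                                    tempos_ms = tempos_ms,
                                    dmax_range = dmax_range,
                                    lag_sd = lag_sd, params = params)))
}

#' Experiment 2: intrinsic patterns, stability and adaptability
#'
#' Simulates a cohort of intermediate jugglers (free-tempo trials plus
#' up/down tempo ramps), summarizes each participant (intrinsic-pattern
#' CPI, RQA indices, %Asynchrony), and computes the three correlation
#' families: CPI vs RQA (12 analyses, Bonferroni k = 12), CPI vs
#' %Asynchrony (k = 2), and %Asynchrony vs RQA per ramp direction
#' (k = 12). A Shapiro-Wilk gate on the variables selects Spearman when
#' normality is rejected.
#'
#' @param n_participants cohort size (default 10).
#' @param d_values dwell fractions (default evenly spanning 0-0.6).
#' @param adaptability_coupling see [simulate_cohort()].
#' @param n_trials trials per condition (default 3).
#' @param seed integer seed.
#' @param params an [analysis_params()] list.
#' @return list of tables: `summary` (per participant), `cpi_rqa`,
#'   `cpi_asyn`, `asyn_rqa`, `alpha` levels, `manifest`.
#' @export
run_experiment2 <- function(n_participants = 10,
                            d_values = seq(0, 0.6,
                                           length.out = n_participants),
                            adaptability_coupling = 0.04,
                            n_trials = 3, seed = 1,
                            params = analysis_params()) {
  cohort <- simulate_cohort(n_participants, d_values,
                            adaptability_coupling, seed = seed,
                            n_trials = n_trials)
  summary_df <- cohort_summary(cohort, params)

  gate_with <- function(yvars) {
    vars <- c(list(summary_df$cpi),
              lapply(yvars, function(v) summary_df[[v]]))
    tryCatch(normality_gate(vars), error = function(e) "spearman")
  }
  rqa_cols <- as.vector(outer(c("rec", "det", "maxline"), params$channels,
                              paste, sep = "_"))
  method_rqa <- gate_with(rqa_cols)
  cpi_rqa <- rqa_index_correlations(summary_df, "cpi", params$channels,
                                    method_rqa, "cpi_vs_rqa")

  method_asyn <- gate_with(c("asyn_up", "asyn_down"))
  cpi_asyn <- do.call(rbind, lapply(c("asyn_up", "asyn_down"), function(v) {
    ct <- correlation_test(summary_df$cpi, summary_df[[v]], method_asyn)
    data.frame(analysis = "cpi_vs_asynchrony",
               condition = sub("asyn_", "", v), method = ct$method,
               n = ct$n, r = ct$r, p = ct$p)
  }))

  asyn_rqa <- do.call(rbind, lapply(c("asyn_up", "asyn_down"), function(v) {
    out <- rqa_index_correlations(summary_df, v, params$channels,
                                  method_rqa, "asynchrony_vs_rqa")
    out$condition <- sub("asyn_", "", v)
    out
  }))

  a12 <- bonferroni_alpha(0.05, 12)
  a2 <- bonferroni_alpha(0.05, 2)
  list(summary = summary_df, cpi_rqa = cpi_rqa, cpi_asyn = cpi_asyn,
       asyn_rqa = asyn_rqa,
       alpha = list(
         rqa = list(level = a12, printed = format_alpha_percent(a12), k = 12),
         asyn = list(level = a2, printed = format_alpha_percent(a2), k = 2)),
       manifest = run_manifest("exp2", seed,
                               list(n_participants = n_participants,
                                    d_values = d_values,
                                    adaptability_coupling = adaptability_coupling,
                                    n_trials = n_trials, params = params)))
}

run_manifest <- function(experiment, seed, config) {
  list(experiment = experiment, seed = seed,
       package_version = as.character(utils::packageVersion("coordrqa")),
       config = config)
}

# ---------------------------------------------------------------------------
# Trial I/O: one CSV per trial for markers, a single-column text file for
# beep onsets, a CSV for events, and a YAML manifest for cohorts.

#' Write a trial to plain-text files
#'
#' Writes `<prefix>_markers.csv` (columns `time_s`, `marker_id`, `x_mm`,
#' `y_mm`, `z_mm`), `<prefix>_beeps.txt` (one onset in seconds per
#' line; absent for free-tempo trials), and `<prefix>_events.csv`
#' (columns `hand`, `type`, `time_s`).
#'
#' @param trial a `trial_bundle`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix (default `"trial"`).
#' @return invisibly, the paths written.
#' @export
write_trial <- function(trial, dir, prefix = "trial") {
  stopifnot(inherits(trial, "trial_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  markers <- do.call(rbind, lapply(
    c("head", "wrist_left", "wrist_right"), function(id) {
      m <- trial[[id]]
      data.frame(time_s = trial$time, marker_id = id,
                 x_mm = m[, "x"], y_mm = m[, "y"], z_mm = m[, "z"])
    }))
  pm <- file.path(dir, paste0(prefix, "_markers.csv"))
  write.csv(markers, pm, row.names = FALSE)
  paths <- pm
  if (length(trial$beeps$onsets) > 0) {
    pb <- file.path(dir, paste0(prefix, "_beeps.txt"))
    writeLines(format(trial$beeps$onsets, digits = 10), pb)
    paths <- c(paths, pb)
  }
  ev <- data.frame(hand = trial$events$hands, type = "catch",
                   time_s = trial$events$catch_times)
  pe <- file.path(dir, paste0(prefix, "_events.csv"))
  write.csv(ev, pe, row.names = FALSE)
  invisible(c(paths, pe))
}

#' Read a trial from plain-text files
#'
#' Counterpart of [write_trial()]; positions round-trip to better than
#' 1e-6 mm. Rejects files with missing columns, non-finite values, or a
#' non-monotone time axis.
#'
#' @param dir directory holding the files.
#' @param prefix file-name prefix used when writing.
#' @param condition condition label for the rebuilt trial; the beep
#'   train is rebuilt as a fixed train when onsets are equally spaced,
#'   otherwise kept as raw onsets.
#' @return a `trial_bundle`.
#' @export
read_trial <- function(dir, prefix = "trial", condition = NULL) {
  pm <- file.path(dir, paste0(prefix, "_markers.csv"))
  if (!file.exists(pm)) stop_format(paste("missing marker file:", pm))
  markers <- tryCatch(read.csv(pm, stringsAsFactors = FALSE),
                      error = function(e)
                        stop_format(paste("unreadable marker file:",
                                          conditionMessage(e))))
  need <- c("time_s", "marker_id", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(markers))
  if (length(miss))
    stop_format(paste("marker file lacks column(s):",
                      paste(miss, collapse = ", ")))
  if (nrow(markers) == 0) stop_format("marker file is empty")
  num <- as.matrix(markers[, c("x_mm", "y_mm", "z_mm")])
  if (!all(is.finite(num))) {
    bad <- which(!apply(is.finite(num), 1, all))
    stop_format(sprintf("non-finite marker values at data row(s) %s",
                        paste(head(bad, 5), collapse = ", ")))
  }
  get_marker <- function(id) {
    m <- markers[markers$marker_id == id, , drop = FALSE]
    if (nrow(m) == 0) stop_format(paste("marker missing from file:", id))
    dt <- diff(m$time_s)
    if (any(dt <= 0)) {
      bad <- which(dt <= 0)[1] + 1L
      stop_format(sprintf("non-monotone time for marker %s at data row %d",
                          id, bad))
    }
    list(time = m$time_s,
         xyz = cbind(x = m$x_mm, y = m$y_mm, z = m$z_mm))
  }
  head_m <- get_marker("head")
  wl <- get_marker("wrist_left")
  wr <- get_marker("wrist_right")
  rate <- 1 / median(diff(head_m$time))

  pe <- file.path(dir, paste0(prefix, "_events.csv"))
  if (!file.exists(pe)) stop_format(paste("missing events file:", pe))
  ev <- read.csv(pe, stringsAsFactors = FALSE)
  if (!all(c("hand", "type", "time_s") %in% names(ev)))
    stop_format("events file lacks hand/type/time_s columns")
  cat_ev <- ev[ev$type == "catch", , drop = FALSE]
  events <- event_series(cat_ev$time_s, cat_ev$hand)

  pb <- file.path(dir, paste0(prefix, "_beeps.txt"))
  if (file.exists(pb)) {
    onsets <- as.numeric(readLines(pb))
    if (any(!is.finite(onsets)) || any(diff(onsets) <= 0))
      stop_format("beep onsets must be finite and strictly increasing")
    ints <- diff(onsets) * 1000
    beeps <- if (diff(range(ints)) < 1e-6) {
      make_beep_train("fixed", interval_ms = ints[1], n_beeps = length(onsets))
    } else {
      structure(list(onsets = onsets, intervals = ints,
                     condition = if (is.null(condition)) "custom" else condition,
                     note = "read from file"),
                class = "beep_train")
    }
  } else {
    beeps <- make_beep_train("none",
                             duration_s = max(head_m$time))
  }
  structure(
    list(head = head_m$xyz, wrist_left = wl$xyz, wrist_right = wr$xyz,
         beeps = beeps, events = events, rate = rate,
         condition = if (is.null(condition)) beeps$condition else condition,
         pattern = NULL, time = head_m$time),
    class = "trial_bundle"
  )
}

#' Write result tables and a run manifest
#'
#' Writes every data.frame in `results` as `<name>.csv` and, if present,
#' the `manifest` element as `manifest.yaml`.
#'
#' @param results a named list as returned by [run_experiment1()] or
#'   [run_experiment2()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    if (is.data.frame(results[[nm]])) {
      p <- file.path(dir, paste0(nm, ".csv"))
      write.csv(results[[nm]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if (!is.null(results$manifest)) {
    p <- file.path(dir, "manifest.yaml")
    yaml::write_yaml(results$manifest, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
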