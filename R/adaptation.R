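# Sensorimotor-synchronization scoring for ramped-tempo trials:
# %Asynchrony, the absolute catch-to-beep timing error normalized by the
# local inter-beep interval.

#' Pair catches with metronome beeps
#'
#' Sequential (index) pairing: the k-th catch in merged-hand time order
#' is paired with the k-th beep, up to the shorter list (trials truncated
#' by a dropped ball simply yield fewer pairs). Nearest-beep pairing is
#' available but would silently forgive skipped beeps.
#'
#' @param events an [event_series()].
#' @param beeps a [make_beep_train()] with at least one onset.
#' @param pairing `"sequential"` (default) or `"nearest"`.
#' @return data.frame with columns `catch_time`, `beep_time`,
#'   `beep_index`.
#' @export
pair_catches_to_beeps <- function(events, beeps,
                                  pairing = c("sequential", "nearest")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(events, "event_series"), inherits(beeps, "beep_train"))
  catches <- events$catch_times
  onsets <- beeps$onsets
  if (length(catches) == 0 || length(onsets) == 0)
    stop_insufficient("pairing needs at least one catch and one beep")
  if (pairing == "sequential") {
    k <- min(length(catches), length(onsets))
    data.frame(catch_time = catches[seq_len(k)],
               beep_time = onsets[seq_len(k)],
               beep_index = seq_len(k))
  } else {
    idx <- vapply(catches, function(ct) which.min(abs(onsets - ct)),
                  integer(1))
    data.frame(catch_time = catches, beep_time = onsets[idx],
               beep_index = idx)
  }
}

#' Percent asynchrony
#'
#' For each catch-beep pair the asynchrony is the absolute timing error
#' `|catch - beep|`; because the tempo changes within a ramped trial,
#' each error is scaled by the inter-beep interval local to its beep
#' (the interval ending at the paired beep by default), giving a
#' percentage. The first `discard_first` catches are treated as task
#' warm-up and removed; the trial score is the mean percentage over the
#' retained pairs.
#'
#' @param pairs data.frame from [pair_catches_to_beeps()].
#' @param beeps the [make_beep_train()] the pairs refer to (provides the
#'   inter-beep intervals).
#' @param discard_first warm-up catches to drop (default 6).
#' @param interval_side `"preceding"` (default; the interval ending at
#'   the paired beep) or `"following"`.
#' @return an object of class `asynchrony_result`: `per_catch`
#'   data.frame (`catch_time`, `beep_time`, `asynchrony_ms`,
#'   `local_interval_ms`, `percent`), `percent_asynchrony` (mean %),
#'   `n_used`, `n_discarded`.
#' @export
percent_asynchrony <- function(pairs, beeps, discard_first = 6,
                               interval_side = c("preceding", "following")) {
  interval_side <- match.arg(interval_side)
  stopifnot(is.data.frame(pairs), inherits(beeps, "beep_train"))
  if (nrow(pairs) < discard_first + 1)
    stop_insufficient(sprintf(
      "need more than %d pairs to score a trial, got %d",
      discard_first, nrow(pairs)))
  ints <- beeps$intervals # ms, ints[k] spans onset k -> k+1
  nb <- length(beeps$onsets)
  local_int <- vapply(pairs$beep_index, function(k) {
    if (interval_side == "preceding") {
      if (k > 1) ints[k - 1] else ints[1]
    } else {
      if (k < nb) ints[k] else ints[length(ints)]
    }
  }, numeric(1))
  asyn_ms <- 1000 * abs(pairs$catch_time - pairs$beep_time)
  percent <- 100 * asyn_ms / local_int
  per_catch <- data.frame(catch_time = pairs$catch_time,
                          beep_time = pairs$beep_time,
                          asynchrony_ms = asyn_ms,
                          local_interval_ms = local_int,
                          percent = percent)
  keep <- seq_len(nrow(per_catch)) > discard_first
  structure(list(per_catch = per_catch,
                 percent_asynchrony = mean(percent[keep]),
                 n_used = sum(keep), n_discarded = sum(!keep)),
            class = "asynchrony_result")
}

#' @export
print.asynchrony_result <- function(x, ...) {
  cat(sprintf("<asynchrony_result: %%Asynchrony = %.2f%% over %d catches (%d discarded)>\n",
              x$percent_asynchrony, x$n_used, x$n_discarded))
  invisible(x)
}
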