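# Recurrence quantification: thresholded recurrence matrices and the
# three stability indices %REC, %DET, %MAXLINE.
#
# Conventions (all exposed as arguments):
#   * radius = radius_fraction (default 0.15) of the maximum pairwise
#     distance, Euclidean norm;
#   * the "minimum recurrence time" is a Theiler band: cells with
#     |i - j| < theiler (default 10) are excluded from every numerator
#     and denominator;
#   * the matching minimum line length (default 10) gates %DET and the
#     longest line;
#   * %MAXLINE = 100 * Lmax / (N' - theiler), the longest achievable
#     off-band diagonal (alternative denominator N' - 1 selectable);
#   * counting is done on the upper triangle and doubled by symmetry,
#     which leaves all three ratios unchanged.

#' Pairwise distance matrix of an embedded attractor
#'
#' @param attractor an `N' x m` matrix of embedded points (see
#'   [delay_embed()]), `N' >= 2`.
#' @return symmetric `N' x N'` Euclidean distance matrix with zero
#'   diagonal.
#' @export
pairwise_distance_matrix <- function(attractor) {
  pts <- unclass(attractor)
  if (!is.matrix(pts)) pts <- as.matrix(pts)
  if (nrow(pts) < 2) stop_parameter("need at least 2 points")
  if (!all(is.finite(pts)))
    stop_parameter("attractor contains non-finite points")
  dist_matrix_cpp(pts)
}

#' Thresholded recurrence matrix
#'
#' Marks pairs of times whose embedded states lie within the radius
#' `e = radius_fraction * max(distances)` of each other, excluding the
#' Theiler band `|i - j| < theiler` around the main diagonal
#' (temporally trivial neighbors).
#'
#' @param distances symmetric distance matrix from
#'   [pairwise_distance_matrix()].
#' @param radius_fraction radius as a fraction of the maximum pairwise
#'   distance (default 0.15).
#' @param theiler Theiler window / minimum recurrence time, frames
#'   (default 10).
#' @return an object of class `recurrence_matrix`: fields `entries`
#'   (logical `N' x N'`, FALSE throughout the excluded band), `radius`,
#'   `radius_fraction`, `theiler`, `n`.
#' @export
recurrence_matrix <- function(distances, radius_fraction = 0.15,
                              theiler = 10) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (n != ncol(d)) stop_parameter("distances must be square")
  if (radius_fraction <= 0) stop_parameter("radius_fraction must be > 0")
  if (theiler < 1 || theiler != round(theiler))
    stop_parameter("theiler must be a positive integer")
  dmax <- max(d)
  if (dmax <= 0)
    stop_coordrqa("all points coincide: recurrence undefined",
                  "coordrqa_degenerate_input")
  if (theiler >= n)
    stop_coordrqa("Theiler window excludes every cell",
                  "coordrqa_degenerate_input")
  e <- radius_fraction * dmax
  off <- abs(row(d) - col(d)) >= theiler
  structure(list(entries = (d <= e) & off, radius = e,
                 radius_fraction = radius_fraction,
                 theiler = as.integer(theiler), n = n),
            class = "recurrence_matrix")
}

#' @export
print.recurrence_matrix <- function(x, ...) {
  cat(sprintf(
    "<recurrence_matrix: %d x %d, radius %.4g (%.0f%% of max), theiler %d>\n",
    x$n, x$n, x$radius, 100 * x$radius_fraction, x$theiler))
  invisible(x)
}

#' Diagonal line-length histogram
#'
#' Counts the maximal runs of recurrent cells along every off-band
#' diagonal of the upper triangle (the lower triangle is its mirror).
#' Runs shorter than `min_line` are kept in the histogram but flagged
#' sub-threshold.
#'
#' @param rm a [recurrence_matrix()].
#' @param min_line minimum diagonal line length (default 10).
#' @return data.frame with columns `length`, `count`, `qualifies`.
#' @export
diagonal_line_histogram <- function(rm, min_line = 10) {
  stopifnot(inherits(rm, "recurrence_matrix"))
  n <- rm$n
  runs <- integer(0)
  for (k in seq(rm$theiler, n - 1)) {
    i <- seq_len(n - k)
    diagk <- rm$entries[cbind(i, i + k)]
    r <- rle(diagk)
    runs <- c(runs, r$lengths[r$values])
  }
  if (length(runs) == 0)
    return(data.frame(length = integer(0), count = integer(0),
                      qualifies = logical(0)))
  tab <- table(runs)
  len <- as.integer(names(tab))
  data.frame(length = len, count = as.integer(tab),
             qualifies = len >= min_line)
}

new_rqa_metrics <- function(rec, det, maxline, histogram, params) {
  structure(list(rec = rec, det = det, maxline = maxline,
                 histogram = histogram, params = params),
            class = "rqa_metrics")
}

#' @export
print.rqa_metrics <- function(x, ...) {
  cat(sprintf("<rqa_metrics: %%REC = %.3g, %%DET = %s, %%MAXLINE = %.3g>\n",
              x$rec, if (is.na(x$det)) "undefined" else sprintf("%.3g", x$det),
              x$maxline))
  invisible(x)
}

rqa_assemble <- function(recur, valid, det_pts, lmax_any, lmax_q,
                         n, theiler, min_line, radius, radius_fraction,
                         histogram,
                         maxline_denom = c("n_minus_theiler", "n_minus_one"),
                         lmax_rule = c("qualifying", "any")) {
  maxline_denom <- match.arg(maxline_denom)
  lmax_rule <- match.arg(lmax_rule)
  rec <- 100 * recur / valid
  det <- if (recur > 0) 100 * det_pts / recur else NA_real_
  lmax <- if (lmax_rule == "qualifying") lmax_q else lmax_any
  denom <- if (maxline_denom == "n_minus_theiler") n - theiler else n - 1
  maxline <- 100 * lmax / denom
  new_rqa_metrics(rec, det, maxline, histogram,
                  list(n = n, theiler = theiler, min_line = min_line,
                       radius = radius, radius_fraction = radius_fraction,
                       lmax = lmax, maxline_denom = maxline_denom,
                       lmax_rule = lmax_rule))
}

#' RQA metrics from a recurrence matrix
#'
#' * `%REC`: recurrent cells as a percentage of all valid (off-band)
#'   cells — overall trajectory revisitation.
#' * `%DET`: percentage of recurrent cells lying on diagonal lines of at
#'   least `min_line` cells — deterministic structure. Undefined (`NA`)
#'   when there are no recurrent cells.
#' * `%MAXLINE`: longest qualifying diagonal line as a percentage of the
#'   longest achievable one — attractor strength.
#'
#' @param rm a [recurrence_matrix()].
#' @param min_line minimum diagonal line length (default 10).
#' @param maxline_denom `"n_minus_theiler"` (default) or `"n_minus_one"`.
#' @param lmax_rule `"qualifying"` (default; lines shorter than
#'   `min_line` do not count, so `%MAXLINE` is 0 when none qualifies) or
#'   `"any"`.
#' @return an object of class `rqa_metrics` with fields `rec`, `det`,
#'   `maxline`, `histogram`, `params`.
#' @export
rqa_metrics <- function(rm, min_line = 10,
                        maxline_denom = c("n_minus_theiler", "n_minus_one"),
                        lmax_rule = c("qualifying", "any")) {
  stopifnot(inherits(rm, "recurrence_matrix"))
  hist <- diagonal_line_histogram(rm, min_line)
  n <- rm$n
  valid <- sum(n - seq(rm$theiler, n - 1))
  recur <- sum(rm$entries[upper.tri(rm$entries)])
  det_pts <- sum(hist$length[hist$qualifies] * hist$count[hist$qualifies])
  lmax_any <- if (nrow(hist)) max(hist$length) else 0L
  lmax_q <- if (any(hist$qualifies)) max(hist$length[hist$qualifies]) else 0L
  rqa_assemble(recur, valid, det_pts, lmax_any, lmax_q, n, rm$theiler,
               min_line, rm$radius, rm$radius_fraction, hist,
               maxline_denom, lmax_rule)
}

#' One-shot RQA of an embedded attractor
#'
#' Computes the same `%REC`/`%DET`/`%MAXLINE` as building the full
#' recurrence matrix with [recurrence_matrix()] and calling
#' [rqa_metrics()], but streams over the pair distances in compiled code
#' without materializing the `N' x N'` matrix, so full-size (2500-point)
#' trials are cheap.
#'
#' @param attractor an `N' x m` matrix of embedded points.
#' @param radius_fraction radius as a fraction of the maximum pairwise
#'   distance (default 0.15).
#' @param theiler Theiler window, frames (default 10).
#' @param min_line minimum diagonal line length (default 10).
#' @inheritParams rqa_metrics
#' @return an `rqa_metrics` object.
#' @export
rqa_analyze <- function(attractor, radius_fraction = 0.15, theiler = 10,
                        min_line = 10,
                        maxline_denom = c("n_minus_theiler", "n_minus_one"),
                        lmax_rule = c("qualifying", "any")) {
  pts <- unclass(attractor)
  if (!is.matrix(pts)) pts <- as.matrix(pts)
  if (!all(is.finite(pts)))
    stop_parameter("attractor contains non-finite points")
  if (radius_fraction <= 0) stop_parameter("radius_fraction must be > 0")
  if (theiler < 1 || theiler != round(theiler))
    stop_parameter("theiler must be a positive integer")
  n <- nrow(pts)
  if (theiler >= n)
    stop_coordrqa("Theiler window excludes every cell",
                  "coordrqa_degenerate_input")
  cnt <- rqa_count(pts, radius_fraction, as.integer(theiler),
                   as.integer(min_line))
  if (isTRUE(cnt$degenerate))
    stop_coordrqa("all points coincide: recurrence undefined",
                  "coordrqa_degenerate_input")
  hist <- data.frame(length = cnt$run_length, count = as.integer(cnt$run_count),
                     qualifies = cnt$run_length >= min_line)
  hist <- hist[hist$count > 0, , drop = FALSE]
  rqa_assemble(cnt$recurrent_upper, cnt$valid_upper, cnt$det_points_upper,
               cnt$lmax_any, cnt$lmax_qualifying, n, as.integer(theiler),
               min_line, cnt$radius, radius_fraction, hist,
               maxline_denom, lmax_rule)
}

#' Participant-level RQA metrics
#'
#' Element-wise mean of the left- and right-hand metrics; if either side
#' has an undefined `%DET`, the result's `%DET` is undefined and a
#' warning is raised.
#'
#' @param left,right `rqa_metrics` objects.
#' @return an `rqa_metrics` object (histogram dropped).
#' @export
participant_rqa <- function(left, right) {
  stopifnot(inherits(left, "rqa_metrics"), inherits(right, "rqa_metrics"))
  det <- if (is.na(left$det) || is.na(right$det)) {
    warning("%DET undefined for one hand; propagating undefined")
    NA_real_
  } else mean(c(left$det, right$det))
  new_rqa_metrics(mean(c(left$rec, right$rec)), det,
                  mean(c(left$maxline, right$maxline)), NULL,
                  list(averaged_over = "hands"))
}
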