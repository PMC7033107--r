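# Attractor reconstruction by time-delay embedding: delay selection via
# the first local minimum of average mutual information, dimension
# selection via false nearest neighbors, and construction of the delay
# vectors.

#' Average mutual information curve
#'
#' AMI between a series and its lagged copy, in bits, estimated from an
#' `n_bins` x `n_bins` equal-width joint histogram of `(x_t, x_{t+lag})`
#' with bin edges spanning the full range of the series. The first local
#' minimum of this curve is the standard choice of embedding delay.
#'
#' @param signal a [sampled_signal()] or numeric vector.
#' @param max_lag largest lag, in frames.
#' @param n_bins number of histogram bins per axis (default 16).
#' @return a data.frame with columns `lag` (0..max_lag) and `ami` (bits).
#' @export
average_mutual_information <- function(signal, max_lag, n_bins = 16) {
  x <- as_signal_values(signal)
  n <- length(x)
  if (n_bins < 4) stop_parameter("n_bins must be >= 4")
  if (max_lag < 1 || max_lag >= n - 1)
    stop_parameter("max_lag must satisfy 1 <= max_lag < length - 1")
  rng <- range(x)
  if (diff(rng) == 0)
    stop_coordrqa("constant signal: AMI undefined (zero-entropy marginal)",
                  "coordrqa_degenerate_input")
  # bin index in 1..n_bins, equal-width over the full range
  bin <- pmin(pmax(floor((x - rng[1]) / diff(rng) * n_bins) + 1L, 1L), n_bins)
  ami <- vapply(0:max_lag, function(lag) {
    a <- bin[seq_len(n - lag)]
    b <- bin[seq_len(n - lag) + lag]
    joint <- tabulate((a - 1L) * n_bins + b, nbins = n_bins * n_bins)
    joint <- joint / sum(joint)
    pa <- tabulate(a, nbins = n_bins) / length(a)
    pb <- tabulate(b, nbins = n_bins) / length(b)
    pp <- outer(pa, pb)
    nz <- joint > 0
    sum(joint[nz] * log2(joint[nz] / as.vector(t(pp))[nz]))
  }, numeric(1))
  data.frame(lag = 0:max_lag, ami = ami)
}

#' Select the embedding delay
#'
#' The delay is the lag of the first local minimum of the AMI curve: the
#' smallest lag `l >= 1` with `ami(l-1) > ami(l) <= ami(l+1)`. If the
#' curve has no local minimum the lag of the global minimum (excluding
#' lag 0) is returned with a warning.
#'
#' @param ami_curve data.frame from [average_mutual_information()].
#' @return selected delay, frames.
#' @export
select_delay <- function(ami_curve) {
  stopifnot(is.data.frame(ami_curve), nrow(ami_curve) >= 3)
  a <- ami_curve$ami
  lags <- ami_curve$lag
  for (i in 2:(length(a) - 1)) {
    if (a[i - 1] > a[i] && a[i] <= a[i + 1]) return(lags[i])
  }
  warning("AMI curve has no local minimum; returning its global minimum lag")
  cand <- which(lags >= 1)
  lags[cand][which.min(a[cand])]
}

#' False nearest neighbors fractions
#'
#' For each dimension `m`, the fraction of embedded points whose nearest
#' neighbor in dimension `m` becomes "false" when the embedding is
#' extended to `m + 1`: either the added coordinate separates the pair by
#' more than `Rtol` times their m-dimensional distance, or the extended
#' distance exceeds `Atol` times the attractor size (the sd of the
#' series). The fraction drops to ~0 once the attractor is unfolded.
#'
#' @param signal a [sampled_signal()] or numeric vector.
#' @param tau embedding delay, frames.
#' @param max_m largest dimension tested (fractions are reported for
#'   m = 1..max_m, each requiring coordinates up to m+1).
#' @param Rtol distance-ratio threshold (default 15).
#' @param Atol attractor-size threshold (default 2).
#' @return data.frame with columns `m` and `fraction`.
#' @export
false_nearest_neighbors <- function(signal, tau, max_m = 8,
                                    Rtol = 15, Atol = 2) {
  x <- as_signal_values(signal)
  n <- length(x)
  if (tau < 1 || max_m < 1) stop_parameter("tau and max_m must be >= 1")
  RA <- sd(x)
  fractions <- vapply(seq_len(max_m), function(m) {
    npts <- n - m * tau # need the (m+1)-th coordinate x[i + m*tau]
    if (npts < 10)
      stop_insufficient(sprintf(
        "only %d usable points for m = %d at tau = %d (need >= 10)",
        max(npts, 0), m, tau))
    emb <- delay_embed(x[seq_len(npts + (m - 1) * tau)], tau, m)
    dm <- as.matrix(stats::dist(emb))
    diag(dm) <- Inf
    nn <- max.col(-dm, ties.method = "first")
    rm_ <- dm[cbind(seq_len(npts), nn)]
    extra <- abs(x[seq_len(npts) + m * tau] - x[nn + m * tau])
    # noise floor: for numerically identical states (rm ~ rounding error,
    # as in exactly periodic signals) the distance ratio is a quotient of
    # rounding errors; require the added coordinate to separate the pair
    # by more than the floor before calling it false
    tol <- 1e3 * .Machine$double.eps * RA
    ratio_false <- extra > pmax(Rtol * rm_, tol)
    size_false <- sqrt(rm_^2 + extra^2) / RA > Atol
    mean(ratio_false | size_false)
  }, numeric(1))
  data.frame(m = seq_len(max_m), fraction = fractions)
}

#' Select the embedding dimension
#'
#' Smallest dimension whose false-nearest-neighbor fraction is at or
#' below `cutoff`; if none qualifies, the largest tested dimension is
#' returned with a warning.
#'
#' @param fractions data.frame from [false_nearest_neighbors()] or a
#'   numeric vector of fractions for m = 1, 2, ...
#' @param cutoff FNN fraction cutoff (default 0.01).
#' @return selected dimension.
#' @export
select_dimension <- function(fractions, cutoff = 0.01) {
  if (is.data.frame(fractions)) {
    m <- fractions$m
    f <- fractions$fraction
  } else {
    f <- as.numeric(fractions)
    m <- seq_along(f)
  }
  if (length(f) == 0) stop_parameter("fractions must be non-empty")
  ok <- which(f <= cutoff)
  if (length(ok) == 0) {
    warning("no dimension reaches the FNN cutoff; returning the largest tested")
    return(m[length(m)])
  }
  m[min(ok)]
}

#' Time-delay embedding
#'
#' Builds the delay vectors
#' `(x_i, x_{i+tau}, ..., x_{i+(m-1)tau})`, `i = 1..N - (m-1)tau`, which
#' reconstruct the system's attractor from the scalar series.
#'
#' @param signal a [sampled_signal()] or numeric vector of length `N`.
#' @param tau delay, frames (>= 1).
#' @param m embedding dimension (>= 1).
#' @return an `N' x m` numeric matrix of class `embedded_attractor` with
#'   `N' = N - (m-1) * tau` rows and attributes `tau`, `m`.
#' @export
delay_embed <- function(signal, tau, m) {
  x <- as_signal_values(signal)
  n <- length(x)
  if (tau < 1 || tau != round(tau)) stop_parameter("tau must be a positive integer")
  if (m < 1 || m != round(m)) stop_parameter("m must be a positive integer")
  np <- n - (m - 1) * tau
  if (np < 1)
    stop_insufficient(sprintf(
      "series of length %d too short for m = %d, tau = %d (need > %d samples)",
      n, m, tau, (m - 1) * tau))
  pts <- vapply(seq_len(m), function(j) x[seq_len(np) + (j - 1) * tau],
                numeric(np))
  if (np == 1) pts <- matrix(pts, nrow = 1)
  structure(pts, tau = as.integer(tau), m = as.integer(m),
            class = c("embedded_attractor", "matrix", "array"))
}
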