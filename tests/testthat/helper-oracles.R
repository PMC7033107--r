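# Independent reference implementations used as oracles. These are
# deliberately naive direct-definition double loops, sharing no code
# with the package's streaming/compiled paths.

naive_dist_matrix <- function(pts) {
  n <- nrow(pts)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- sqrt(sum((pts[i, ] - pts[j, ])^2))
  d
}

naive_rqa <- function(pts, radius_fraction = 0.15, theiler = 10,
                      min_line = 10) {
  d <- naive_dist_matrix(pts)
  n <- nrow(d)
  e <- radius_fraction * max(d)
  valid <- 0L; rec_cells <- 0L; det_pts <- 0L; lmax <- 0L
  for (k in seq(theiler, n - 1)) {
    run <- 0L
    for (i in seq_len(n - k)) {
      valid <- valid + 1L
      r <- d[i, i + k] <= e
      if (r) { rec_cells <- rec_cells + 1L; run <- run + 1L }
      if ((!r || i == n - k) && run > 0L) {
        if (run >= min_line) {
          det_pts <- det_pts + run
          if (run > lmax) lmax <- run
        }
        run <- 0L
      }
    }
  }
  list(rec = 100 * rec_cells / valid,
       det = if (rec_cells > 0) 100 * det_pts / rec_cells else NA_real_,
       maxline = 100 * lmax / (n - theiler),
       recurrence = (d <= e) & (abs(row(d) - col(d)) >= theiler))
}

# a sampled sine as a sampled_signal
sine_signal <- function(freq = 1, rate = 100, n = 2500, amp = 1) {
  sampled_signal(amp * sin(2 * pi * freq * (0:(n - 1)) / rate), rate)
}
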