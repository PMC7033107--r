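test_that("thinning keeps every factor-th sample and divides the rate", {
  s <- sampled_signal(1:1000, 1000)
  d <- downsample_thinning(s, 10)
  expect_equal(d$rate, 100)
  expect_length(d$values, 100)
  expect_equal(d$values, as.numeric(seq(1, 1000, by = 10)))
  expect_equal(downsample_thinning(s, 1)$values, s$values)
  expect_error(downsample_thinning(s, 0), class = "coordrqa_parameter_error")
})

test_that("residual analysis finds a cutoff above the signal band, below the noise", {
  set.seed(1)
  t <- (0:999) / 100
  s <- sampled_signal(30 * sin(2 * pi * 2 * t) + rnorm(1000, 0, 1), 100)
  fc <- residual_cutoff(s, seq(2, 20, by = 1))
  expect_gt(fc, 2)
  expect_lt(fc, 20)
})

test_that("residual analysis degrades gracefully on noiseless input", {
  t <- (0:999) / 100
  s <- sampled_signal(30 * sin(2 * pi * 2 * t), 100)
  expect_warning(fc <- residual_cutoff(s, seq(2, 20, by = 1)))
  expect_equal(fc, 2)
})

test_that("chosen cutoff is stable under doubling the noise level", {
  t <- (0:999) / 100
  base <- 30 * sin(2 * pi * 2 * t)
  cand <- seq(2, 20, by = 1)
  picks <- sapply(1:30, function(s) {
    set.seed(s)
    n <- rnorm(1000)
    f1 <- residual_cutoff(sampled_signal(base + n, 100), cand)
    f2 <- residual_cutoff(sampled_signal(base + 2 * n, 100), cand)
    abs(f1 - f2)
  })
  expect_lte(stats::median(picks), 2)
  expect_gt(mean(picks <= 2), 0.8)
})

test_that("zero-phase Butterworth passes the band and stops the stopband", {
  t <- (0:1999) / 200
  dc <- sampled_signal(rep(5, 2000), 200)
  expect_equal(butterworth_filter(dc, 10)$values, rep(5, 2000),
               tolerance = 1e-6)
  lo <- sampled_signal(sin(2 * pi * 1 * t), 200)
  out <- butterworth_filter(lo, 10)
  amp <- max(out$values[500:1500])
  expect_equal(amp, 1, tolerance = 0.01)
  hi <- sampled_signal(sin(2 * pi * 40 * t), 200)
  out2 <- butterworth_filter(hi, 5)
  expect_lt(max(abs(out2$values[500:1500])), 0.1)
  expect_error(butterworth_filter(lo, 150), class = "coordrqa_parameter_error")
})

test_that("differentiation is exact on ramps and accurate on slow sines", {
  t <- (0:999) / 100
  ramp <- sampled_signal(3.5 * t, 100)
  expect_equal(differentiate(ramp)$values[2:999], rep(3.5, 998))
  s <- sampled_signal(2 * sin(2 * pi * 1.5 * t), 100)
  v <- differentiate(s)$values
  expect_equal(max(abs(v[100:900])), 2 * 2 * pi * 1.5, tolerance = 0.01)
  cst <- sampled_signal(rep(7, 100), 100)
  expect_equal(differentiate(cst)$values, rep(0, 100))
})

test_that("head-wrist distance is Euclidean and translation invariant", {
  n <- 50
  head <- cbind(x = rep(0, n), y = rep(0, n), z = rep(0, n))
  wrist <- cbind(x = rep(3, n), y = rep(4, n), z = rep(0, n))
  d <- head_wrist_distance(head, wrist)
  expect_equal(d$values, rep(5, n))
  expect_equal(head_wrist_distance(head, head)$values, rep(0, n))
  shift <- matrix(rep(c(10, -20, 5), each = n), n)
  d2 <- head_wrist_distance(head + shift, wrist + shift)
  expect_equal(d2$values, d$values)
  expect_error(head_wrist_distance(head[1:10, ], wrist),
               class = "coordrqa_shape_error")
})

test_that("length standardization interpolates linearly and exactly at ends", {
  t <- (0:2499) / 100
  s <- sampled_signal(sin(2 * pi * t), 100)
  same <- standardize_length(s, 2500)
  expect_equal(same$values, s$values, tolerance = 1e-12)
  ramp <- sampled_signal(2 * (0:999) / 100, 100)
  out <- standardize_length(ramp, 777)
  tt <- seq(0, 9.99, length.out = 777)
  expect_equal(out$values, 2 * tt, tolerance = 1e-12)
  expect_equal(out$values[1], ramp$values[1])
  expect_equal(out$values[777], ramp$values[1000])
  # 25 cycles onto 2500 points = 100 points per cycle
  s25 <- sampled_signal(sin(2 * pi * (0:1249) / 50), 100) # 25 cycles @ 50 f
  std <- standardize_length(s25, 2500)
  expect_length(std$values, 2500)
  ac <- stats::acf(std$values, lag.max = 150, plot = FALSE)$acf[-1]
  expect_equal(49 + which.max(ac[50:150]), 100)
  expect_error(standardize_length(s, 1), class = "coordrqa_parameter_error")
})

test_that("cycle extraction takes 25 same-hand cycles after the warm-up", {
  p <- pattern_params(1, 0, noise_sd = 0)
  tr <- simulate_trial(p, make_beep_train("fixed", interval_ms = 500),
                       seed = 2)
  catches <- hand_catches(tr$events, "left")
  s <- sampled_signal(tr$wrist_left[, "y"], 100)
  seg <- extract_cycles(s, catches, n_cycles = 25, skip = 2)
  dur <- (length(seg$values) - 1) / seg$rate
  expect_equal(dur, 25 * 1, tolerance = 1 / 100 + 1e-9)
  expect_equal(seg$t0, catches[3], tolerance = 1 / 100)
  err <- tryCatch(extract_cycles(s, catches[1:21], n_cycles = 25),
                  error = function(e) e)
  expect_s3_class(err, "coordrqa_insufficient_data")
  expect_match(conditionMessage(err), "20")
})
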