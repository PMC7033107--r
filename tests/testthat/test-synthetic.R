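test_that("fixed beep trains have the protocol's count and spacing", {
  tr <- make_beep_train("fixed", interval_ms = 500)
  expect_length(tr$onsets, 65)
  expect_equal(diff(tr$onsets), rep(0.5, 64))
  tr2 <- make_beep_train("fixed", interval_ms = 1000)
  expect_equal(tr2$onsets[1:2], c(0, 1))
  expect_error(make_beep_train("fixed", interval_ms = -5),
               class = "coordrqa_parameter_error")
  expect_error(make_beep_train("fixed", interval_ms = 50),
               class = "coordrqa_parameter_error")
})

test_that("ramp trains realize 600..303 ms in 3 ms steps and mirror each other", {
  up <- make_beep_train("up_ramp")
  expect_length(up$onsets, 101)
  expect_equal(up$intervals[1], 600)
  expect_equal(up$intervals[100], 303)
  expect_true(all(diff(up$intervals) == -3))
  down <- make_beep_train("down_ramp")
  expect_equal(down$intervals, rev(up$intervals))
  expect_true(all(diff(down$intervals) == 3))
  expect_true(all(diff(up$onsets) > 0))
})

test_that("cycle waveform: sine peak, exact dwell, constant peak-to-peak range", {
  p <- pattern_params(1, amplitude = 100)
  expect_equal(simulate_hand_cycle(p, 0.25), 100)
  pd <- pattern_params(1, dwell_fraction = 0.5, amplitude = 100)
  expect_equal(simulate_hand_cycle(pd, seq(0.5, 0.99, by = 0.01)),
               rep(0, 50))
  tt <- seq(0, 0.999, by = 0.001)
  for (d in c(0, 0.2, 0.5, 0.8)) {
    y <- simulate_hand_cycle(pattern_params(1, d, amplitude = 100), tt)
    expect_equal(max(y) - min(y), 200, tolerance = 1e-3)
  }
  expect_error(simulate_hand_cycle(p, 1.2), class = "coordrqa_parameter_error")
})

test_that("dwell waveform concentrates less power at the cycle frequency", {
  # oracle: direct fft periodogram of the repeated one-cycle waveform
  tt <- seq(0, 0.99, by = 0.01)
  frac_at_f0 <- function(d) {
    y1 <- simulate_hand_cycle(pattern_params(1, d), tt)
    y <- rep(y1, 20)
    p <- Mod(fft(y))^2
    p <- p[2:(length(y) / 2)] # one side, DC dropped
    p[20] / sum(p) # bin 20 = 1 Hz for a 20 s record
  }
  expect_lt(frac_at_f0(0.5), frac_at_f0(0))
  expect_gt(frac_at_f0(0), 0.99)
})

test_that("trials anchor one catch per beep with alternating hands", {
  p <- pattern_params(1, 0.3)
  beeps <- make_beep_train("fixed", interval_ms = 500)
  tr <- simulate_trial(p, beeps, lag_mean = 0, lag_sd = 0, seed = 1)
  expect_equal(tr$events$catch_times, beeps$onsets)
  expect_length(tr$events$catch_times, 65)
  expect_equal(unname(table(tr$events$hands)["left"]), 33)
  expect_equal(unname(table(tr$events$hands)["right"]), 32)
  expect_true(all(tr$events$hands[c(TRUE, FALSE)] == "left"))
  expect_error(simulate_trial(p, beeps, lag_sd = -1),
               class = "coordrqa_parameter_error")
})

test_that("identical seeds give bit-identical trials", {
  p <- pattern_params(0.9, 0.4)
  beeps <- make_beep_train("up_ramp")
  t1 <- simulate_trial(p, beeps, lag_mean = 0.01, lag_sd = 0.02, seed = 99)
  t2 <- simulate_trial(p, beeps, lag_mean = 0.01, lag_sd = 0.02, seed = 99)
  expect_identical(t1$wrist_left, t2$wrist_left)
  expect_identical(t1$head, t2$head)
  expect_identical(t1$events$catch_times, t2$events$catch_times)
  t3 <- simulate_trial(p, beeps, lag_mean = 0.01, lag_sd = 0.02, seed = 100)
  expect_false(identical(t1$wrist_left, t3$wrist_left))
})

test_that("noiseless fixed-tempo wrist movement is periodic at the cycle duration", {
  p <- pattern_params(1, 0.3, noise_sd = 0)
  tr <- simulate_trial(p, make_beep_train("fixed", interval_ms = 500),
                       seed = 5)
  y <- tr$wrist_left[, "y"]
  y <- y[500:2500] - mean(y[500:2500])
  ac <- stats::acf(y, lag.max = 150, plot = FALSE)$acf[-1]
  # first substantial autocorrelation peak at one cycle = 100 frames
  peak <- 49 + which.max(ac[50:150])
  expect_lte(abs(peak - 100), 1)
})

test_that("cohort coupling links discreteness to ramp timing noise", {
  co0 <- simulate_cohort(3, d_values = c(0, 0.3, 0.6),
                         adaptability_coupling = 0, seed = 1, n_trials = 1)
  expect_equal(length(unique(vapply(co0, `[[`, numeric(1), "sigma_ramp"))), 1L)
  # with coupling on, the rhythmic end of the continuum mistimes more:
  # Monte-Carlo over cohorts, comparing mean up-ramp %Asynchrony
  asyn <- sapply(1:25, function(s) {
    co <- simulate_cohort(2, d_values = c(0, 0.6),
                          adaptability_coupling = 0.04, seed = 100 + s,
                          n_trials = 1)
    vapply(co, function(p) trial_asynchrony(p$trials$up_ramp[[1]]),
           numeric(1))
  })
  expect_gt(mean(asyn[1, ]), mean(asyn[2, ]))
  expect_error(simulate_cohort(3, d_values = c(0, 1)),
               class = "coordrqa_parameter_error")
})

test_that("cohort CPI spans a wide range across the dwell grid", {
  co <- simulate_cohort(10, seed = 7, n_trials = 1)
  s <- cohort_summary(co, analysis_params(channels = "SI"))
  expect_gt(max(s$cpi) - min(s$cpi), 0.5)
  expect_gt(max(s$cpi), 0.9) # the rhythmic end is nearly pure
})
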