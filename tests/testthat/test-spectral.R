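test_that("periodogram localizes tones and conserves variance", {
  s <- sine_signal(freq = 1.9, n = 2000)
  ps <- power_spectrum(s)
  expect_equal(ps$freqs[which.max(ps$power)], 1.9, tolerance = 0.05)
  # equal-amplitude tones carry equal power
  x <- sin(2 * pi * 1.9 * (0:1999) / 100) + sin(2 * pi * 3.8 * (0:1999) / 100)
  ps2 <- power_spectrum(sampled_signal(x, 100))
  top2 <- sort(ps2$power, decreasing = TRUE)[1:2]
  expect_equal(top2[1] / top2[2], 1, tolerance = 0.01)
  # Parseval: non-DC power equals mean squared deviation from the mean
  set.seed(4)
  y <- rnorm(1024) + 3
  psy <- power_spectrum(sampled_signal(y, 100))
  expect_equal(sum(psy$power[-1]), mean((y - mean(y))^2), tolerance = 1e-2)
})

test_that("white noise has a flat spectrum on average", {
  set.seed(11)
  acc <- 0
  for (i in 1:50) {
    ps <- power_spectrum(sampled_signal(rnorm(512), 100))
    acc <- acc + ps$power[-1]
  }
  acc <- acc / 50
  lo <- mean(acc[1:85]); hi <- mean(acc[171:255])
  expect_equal(lo / hi, 1, tolerance = 0.1)
})

test_that("fundamental frequency follows the metronome or the spectral peak", {
  expect_equal(fundamental_frequency(make_beep_train("fixed", 260)),
               1 / 0.52, tolerance = 1e-9)
  expect_equal(fundamental_frequency(make_beep_train("fixed", 500)), 1)
  expect_equal(fundamental_frequency(make_beep_train("fixed", 500),
                                     convention = "beep_rate"), 2)
  expect_error(fundamental_frequency(make_beep_train("up_ramp")),
               class = "coordrqa_parameter_error")
  expect_equal(fundamental_frequency(signal = sine_signal(1.5, n = 2000)),
               1.5, tolerance = 0.05)
})

test_that("CPI is 1 for a pure tone and splits evenly for two tones", {
  s <- sine_signal(freq = 1, n = 2500)
  cpi <- coordination_pattern_index(power_spectrum(s), 1)
  expect_equal(cpi$cpi, 1, tolerance = 1e-6)
  x <- sin(2 * pi * (0:2499) / 100) + sin(2 * pi * 2 * (0:2499) / 100)
  cpi2 <- coordination_pattern_index(
    power_spectrum(sampled_signal(x, 100)), 1)
  expect_equal(cpi2$cpi, 0.5, tolerance = 0.01)
})

test_that("CPI decreases with dwell fraction on noiseless waveforms", {
  tt <- seq(0, 0.99, by = 0.01)
  cpi_of_d <- function(d) {
    y <- rep(simulate_hand_cycle(pattern_params(1, d), tt), 25)
    coordination_pattern_index(power_spectrum(sampled_signal(y, 100)), 1)$cpi
  }
  grid <- c(0, 0.15, 0.3, 0.45, 0.6)
  vals <- vapply(grid, cpi_of_d, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(cpi_of_d(0.6), cpi_of_d(0))
})

test_that("CPI is amplitude invariant and monotone in band width", {
  x <- sin(2 * pi * (0:2499) / 100) + 0.5 * sin(2 * pi * 3 * (0:2499) / 100)
  ps1 <- power_spectrum(sampled_signal(x, 100))
  ps2 <- power_spectrum(sampled_signal(17.3 * x, 100))
  c1 <- coordination_pattern_index(ps1, 1)$cpi
  expect_equal(coordination_pattern_index(ps2, 1)$cpi, c1, tolerance = 1e-12)
  widths <- c(0.05, 0.10, 0.20, 0.40)
  cpis <- vapply(widths, function(w)
    coordination_pattern_index(ps1, 1, w)$cpi, numeric(1))
  expect_true(all(diff(cpis) >= 0))
})

test_that("spectrum normalization maps the fundamental to 1 and round-trips", {
  ps <- power_spectrum(sine_signal(freq = 2, n = 1000))
  nz <- normalize_spectrum(ps, 2)
  expect_equal(nz$freqs[which.max(nz$power)], 1, tolerance = 0.05)
  expect_equal(nz$freqs * 2, ps$freqs)
  back <- normalize_spectrum(nz, 1 / 2)
  expect_equal(back$freqs, ps$freqs)
  expect_equal(back$power, ps$power)
})

test_that("participant CPI is the hand mean", {
  expect_equal(participant_cpi(0.8, 0.6), 0.7)
  expect_equal(participant_cpi(0.42, 0.42), 0.42)
  expect_equal(participant_cpi(0.1, 0.9), participant_cpi(0.9, 0.1))
  expect_error(participant_cpi(1.2, 0.5), class = "coordrqa_parameter_error")
})

test_that("too-coarse spectra raise a resolution error", {
  ps <- power_spectrum(sine_signal(freq = 1, n = 64, rate = 100))
  expect_error(coordination_pattern_index(ps, 1, band_width_fraction = 0.001),
               class = "coordrqa_resolution_error")
})
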