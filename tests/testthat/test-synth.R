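test_that("background generator is deterministic and white in the slope-0 limit", {
  a <- generate_background(2, 256, 10, slope = 0, seed = 7)
  b <- generate_background(2, 256, 10, slope = 0, seed = 7)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data,
                         generate_background(2, 256, 10, slope = 0, seed = 8)$data))
  # white noise: autocorrelation at positive lags near zero
  ac <- stats::acf(a$data[1, ], lag.max = 5, plot = FALSE)$acf[-1]
  expect_lt(max(abs(ac)), 0.05)
  expect_equal(sqrt(mean(a$data[1, ]^2)), 10, tolerance = 1e-6)
})

test_that("spectral shaping gives the requested 1/f slope", {
  bg <- generate_background(1, 256, 120, slope = 1, seed = 3)
  expect_equal(psd_slope(bg$data[1, ], 256), -1, tolerance = 0.15)
  bg2 <- generate_background(1, 256, 120, slope = 2, seed = 3)
  expect_equal(psd_slope(bg2$data[1, ], 256), -2, tolerance = 0.3)
})

test_that("injected oscillations have the requested RMS and touch only listed channels", {
  base <- generate_background(3, 256, 10, slope = 0, seed = 1)
  out <- inject_oscillation(base, 10, 2, rms = 5, channels = 1, seed = 9)
  added <- out$data[1, ] - base$data[1, ]
  expect_equal(sqrt(mean(added^2)), 5, tolerance = 0.05 * 5)
  expect_identical(out$data[2, ], base$data[2, ])
  expect_identical(out$data[3, ], base$data[3, ])
  # zero amplitude is the identity
  expect_identical(inject_oscillation(base, 10, 2, rms = 0)$data, base$data)
  # band outside Nyquist rejected
  expect_error(inject_oscillation(base, 127, 4, rms = 1),
               class = "eegbico_parameter_error")
})

test_that("injected component is spectrally concentrated at its centre", {
  base <- generate_background(1, 256, 40, slope = 0, rms = 0.1, seed = 2)
  out <- inject_oscillation(base, 10, 2, rms = 10, channels = 1, seed = 3)
  ps <- morlet_power(make_epochs(out))
  expect_equal(ps$frequencies[which.max(ps$power[1, ])], 10, tolerance = 1)
})

test_that("qpc triplet injection respects amplitude and determinism", {
  base <- generate_background(1, 256, 10, slope = 0, seed = 1)
  expect_identical(inject_qpc_triplet(base, 6, 9, 1, amp = 0)$data, base$data)
  a <- inject_qpc_triplet(base, 6, 9, 0.5, amp = 2, seed = 4)
  b <- inject_qpc_triplet(base, 6, 9, 0.5, amp = 2, seed = 4)
  expect_identical(a$data, b$data)
  expect_error(inject_qpc_triplet(base, 60, 70, 1, amp = 1),
               class = "eegbico_parameter_error")
  expect_error(inject_qpc_triplet(base, 6, 9, 1.5, amp = 1),
               class = "eegbico_parameter_error")
})

test_that("power superposition holds for spectrally disjoint components", {
  base <- generate_background(1, 256, 60, slope = 1, rms = 5, seed = 11)
  both <- inject_oscillation(base, 10, 2, rms = 4, seed = 12)
  both <- inject_oscillation(both, 25, 4, rms = 3, seed = 13)
  expect_equal(mean(both$data[1, ]^2),
               5^2 + 4^2 + 3^2, tolerance = 0.05 * (25 + 16 + 9))
})

test_that("null coupling shrinks with epoch count", {
  meds <- vapply(c(50, 100, 200), function(ne) {
    ep <- triplet_epochs(0, n_epochs = ne, seed = 21)
    b <- wavelet_bicoherence(ep, grid = bifreq_grid(1, 20))
    median(b$values$value)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("up-down simulation follows the staircase rule and terminates", {
  # deterministic responder, threshold inside (2.00, 3.63): alternation
  s <- simulate_updown(responder(2.5), seed = 1)
  expect_equal(s$trials$force_g, rep(c(2.00, 3.63), 4))
  expect_equal(s$trials$response, rep(c(0L, 1L), 4))
  expect_equal(s$first_change_index, 2L)
  # six stimuli after the first change
  expect_equal(nrow(s$trials), s$first_change_index + 6L)
  # determinism for stochastic responders
  s1 <- simulate_updown(responder(2.5, slope = 4), seed = 33)
  s2 <- simulate_updown(responder(2.5, slope = 4), seed = 33)
  expect_identical(s1$trials, s2$trials)
  expect_error(simulate_updown(responder(2.5), filaments = numeric(0)),
               class = "eegbico_parameter_error")
})

test_that("boundary saturation descends to the floor and is flagged", {
  s <- simulate_updown(responder(0.1), seed = 1)
  expect_true(all(s$trials$response == 1))
  expect_equal(min(s$trials$force_g), 0.41)
  expect_equal(s$saturated, "low")
  s_hi <- simulate_updown(responder(100), seed = 1)
  expect_true(all(s_hi$trials$response == 0))
  expect_equal(s_hi$saturated, "high")
})

test_that("synth_study produces the three-session shape run_pipeline expects", {
  st <- synth_study(n_subjects = 2, n_channels = 3, duration = 8, seed = 9)
  expect_named(st, c("before", "after", "ea"))
  expect_length(st$before, 2)
  expect_s3_class(st$after[[1]], "eegbico_recording")
  expect_equal(st$after[[1]]$session, "after")
  st2 <- synth_study(n_subjects = 2, n_channels = 3, duration = 8, seed = 9)
  expect_identical(st$ea[[2]]$data, st2$ea[[2]]$data)
})
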