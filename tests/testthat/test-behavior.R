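test_that("the standard ladder has mean log spacing 0.224", {
  expect_equal(round(mean_log_interval(filament_ladder()), 3), 0.224)
  expect_equal(mean_log_interval(c(1, 10, 100)), 1)
  expect_equal(mean_log_interval(c(1, 2)), log10(2))
  expect_error(filament_ladder(c(2, 1)), class = "eegbico_parameter_error")
})

test_that("the threshold formula is exact at k = 0 and scales by delta steps", {
  lad <- filament_ladder()
  for (f in lad$forces) expect_equal(pwt_formula(f, 0, lad$delta), f)
  expect_equal(pwt_formula(2.00, 1, 0.224), 2.00 * 10^0.224, tolerance = 1e-12)
  expect_equal(pwt_formula(2.00, 1, 0.224), 3.35, tolerance = 0.005)
  expect_equal(pwt_formula(2.00, -1, 0.224), 2.00 / 10^0.224, tolerance = 1e-12)
})

test_that("the packaged k table matches fresh maximum-likelihood tabulation", {
  kt <- k_table()
  expect_true(all(c("pattern", "k") %in% names(kt)))
  set.seed(3)
  probe <- kt[sample(nrow(kt), 25), ]
  for (i in seq_len(nrow(probe))) {
    expect_equal(probe$k[i], dixon_k(probe$pattern[i]), tolerance = 1e-4)
  }
  # symmetric patterns give opposite-sign corrections
  expect_equal(dixon_k("OXOXOXOX"), -dixon_k("XOXOXOXO"), tolerance = 1e-6)
})

test_that("pwt50 applies table lookup, censoring and explicit k correctly", {
  lad <- filament_ladder()
  s <- simulate_updown(responder(2.5), seed = 1)     # OXOXOXOX at 2.00/3.63
  est <- pwt50(s)
  expect_equal(est$method, "table")
  expect_equal(est$threshold_g, pwt_formula(3.63, est$k, lad$delta))
  expect_gt(est$threshold_g, 2.00)
  expect_lt(est$threshold_g, 3.63)
  # explicit k bypasses the table
  expect_equal(pwt50(s, k = 0)$threshold_g, 3.63)
  # saturated sequences come back censored at the ladder bounds
  low <- pwt50(simulate_updown(responder(0.05), seed = 1))
  expect_equal(low$censored, "low")
  expect_equal(low$threshold_g, 0.41)
  high <- pwt50(simulate_updown(responder(50), seed = 1))
  expect_equal(high$censored, "high")
  expect_equal(high$threshold_g, 15.10)
  # unknown interior pattern is an explicit error
  fake <- eegbico:::new_updown(c(2.00, 3.63, 2.00), c(0L, 1L, 0L))
  expect_error(pwt50(fake), class = "eegbico_pattern_error")
})

test_that("boundary-touching sequences fall back to direct ML", {
  lad <- filament_ladder()
  # threshold below 0.70: descends to the floor, changes there, bounces
  s <- simulate_updown(responder(0.5), seed = 2)
  expect_true(0.41 %in% s$trials$force_g)
  est <- pwt50(s)
  if (is.na(s$saturated)) {
    expect_true(est$method %in% c("ml_direct", "table"))
    expect_lt(est$threshold_g, 1.20)
  }
})

test_that("the estimator recovers interior thresholds within one ladder step", {
  lad <- filament_ladder()
  truths <- c(1.0, 1.5, 3.0, 4.5, 7.0)
  study <- estimator_study(truths, n_reps = 10, seed = 11)
  step <- 10^lad$delta
  expect_true(all(study$mean_est <= truths * step &
                    study$mean_est >= truths / step))
  expect_true(all(study$censored_rate == 0))
  # deterministic responder: single rep is reproducible
  one_a <- estimator_study(2.5, n_reps = 1, seed = 5)
  one_b <- estimator_study(2.5, n_reps = 1, seed = 5)
  expect_identical(one_a, one_b)
})

test_that("pwt50 is monotone in the true threshold for deterministic responders", {
  truths <- c(0.9, 1.6, 2.8, 4.2, 6.5, 10.0)
  ests <- vapply(truths, function(th) {
    pwt50(simulate_updown(responder(th), seed = 3))$threshold_g
  }, numeric(1))
  expect_true(all(diff(ests) >= 0))
})

test_that("ceiling saturation is reported as fully censored", {
  study <- estimator_study(60, n_reps = 5, seed = 9)
  expect_equal(study$censored_rate, 1)
  expect_equal(study$mean_est, 15.10)
})
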