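test_that("band-pass preserves mid-band, rejects mains and DC", {
  rec10 <- sinusoid_recording(10, 1)
  out10 <- bandpass(rec10)
  mid <- 512:2048                       # away from edges
  expect_equal(sd(out10$data[1, mid]), sd(rec10$data[1, mid]), tolerance = 0.05)
  rec50 <- sinusoid_recording(50, 1)
  out50 <- bandpass(rec50)
  expect_lt(sd(out50$data[1, mid]) / sd(rec50$data[1, mid]), 0.1)
  recdc <- recording(matrix(100, 1, 2560), fs = 256)
  expect_lt(abs(mean(bandpass(recdc)$data[1, mid])), 1)
  expect_error(bandpass(rec10, 40, 10), class = "eegbico_parameter_error")
})

test_that("band-pass is zero-phase in the passband", {
  rec <- sinusoid_recording(10, 1)
  out <- bandpass(rec)
  mid <- 512:2048
  # cross-correlation peaks at zero lag
  cc <- stats::ccf(out$data[1, mid], rec$data[1, mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("average rereference zeroes the channel sum and is idempotent", {
  rec <- generate_background(4, 256, 4, seed = 5)
  ref <- rereference_average(rec)
  expect_lt(max(abs(colSums(ref$data))), 1e-9 * max(abs(rec$data)))
  ref2 <- rereference_average(ref)
  expect_equal(ref2$data, ref$data, tolerance = 1e-12)
  # two opposite channels are already average-referenced
  two <- recording(rbind(sin(1:100), -sin(1:100)), fs = 100)
  expect_equal(rereference_average(two)$data, two$data, tolerance = 1e-12)
  expect_error(rereference_average(two, exclude = 1),
               class = "eegbico_parameter_error")
})

test_that("excluded channels take no part in the average reference", {
  # 3 channels with constant values 1, 2, 9; excluding ch3 the mean is 1.5
  rec <- recording(matrix(c(1, 2, 9), 3, 10), fs = 10,
                   labels = c("a", "b", "c"))
  ref <- rereference_average(rec, exclude = "c")
  expect_equal(ref$labels, c("a", "b"))
  expect_equal(unname(ref$data[, 1]), c(-0.5, 0.5))
})

test_that("channel rejection removes exactly the artifact and flat channels", {
  rec <- generate_background(4, 256, 4, seed = 6)
  clean <- reject_channels(rec)
  expect_equal(nrow(clean$report), 0)
  bad <- rec
  bad$data[2, ] <- bad$data[2, ] * 200      # gross amplitude artifact
  bad$data[4, ] <- 0                        # flat
  res <- reject_channels(bad)
  expect_setequal(res$report$label, rec$labels[c(2, 4)])
  expect_equal(res$report$reason[res$report$label == rec$labels[2]], "amplitude")
  expect_equal(res$report$reason[res$report$label == rec$labels[4]], "flat")
  expect_equal(res$recording$labels, rec$labels[c(1, 3)])
  allbad <- recording(matrix(0, 2, 100), fs = 10)
  expect_error(reject_channels(allbad), class = "eegbico_rejection_error")
})

test_that("epoching yields the closed-form count and exact sample copies", {
  rec <- generate_background(2, 256, 10, seed = 4)
  ep <- make_epochs(rec)                                 # 2 s / 75%
  expect_equal(dim(ep$epochs), c(17, 2, 512))            # floor((2560-512)/128)+1
  expect_equal(ep$epochs[1, 1, ], rec$data[1, 1:512])
  expect_equal(ep$epochs[3, 2, ], rec$data[2, 257:768])  # start = 2*128
  ep0 <- make_epochs(rec, 2, overlap = 0)
  expect_equal(dim(ep0$epochs)[1], 5)
  short <- generate_background(1, 256, 1, seed = 1)
  expect_error(make_epochs(short), class = "eegbico_parameter_error")
  expect_error(make_epochs(rec, 2, overlap = 1), class = "eegbico_parameter_error")
})

test_that("epoch rejection drops only outlier epochs", {
  rec <- generate_background(1, 256, 20, seed = 8)
  rec$data[1, 3000:3100] <- rec$data[1, 3000:3100] + 500
  ep <- make_epochs(rec)
  res <- reject_epochs(ep)
  expect_gt(length(res$dropped), 0)
  # the contaminated samples lie in epochs starting 2489..3100 -> indices ~20-24
  expect_true(all(res$dropped >= 18 & res$dropped <= 25))
  expect_equal(dim(res$epochs$epochs)[1], dim(ep$epochs)[1] - length(res$dropped))
})

test_that("resampling preserves a mid-band sinusoid", {
  rec <- sinusoid_recording(10, 1, fs = 512, duration = 4)
  out <- resample_recording(rec, 256)
  expect_equal(out$fs, 256)
  expect_equal(ncol(out$data), 1024)
  mid <- 200:800
  tt <- (mid - 1) / 256
  expect_equal(out$data[1, mid], sin(2 * pi * 10 * tt), tolerance = 0.02)
})
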