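test_that("harmonic-wavelet coefficients concentrate in the right band", {
  x <- sin(2 * pi * 10 * (0:511) / 256)
  W <- harmonic_wavelet_coeffs(x, 256, bifreq_grid(1, 45))
  mags <- rowMeans(Mod(W))
  centers <- bifreq_grid(1, 45)$centers
  expect_lt(mags[centers == 20], 0.05 * max(mags))
  expect_true(centers[which.max(mags)] %in% c(9, 10, 11))
  expect_true(all(harmonic_wavelet_coeffs(numeric(512), 256) == 0))
  # linearity
  W3 <- harmonic_wavelet_coeffs(3 * x, 256, bifreq_grid(1, 45))
  expect_equal(Mod(W3), 3 * Mod(W), tolerance = 1e-9)
  expect_error(harmonic_wavelet_coeffs(x, 256, bifreq_grid(1, 200)),
               class = "eegbico_parameter_error")
})

test_that("bicoherence detects a locked triplet and stays low under the null", {
  ep1 <- triplet_epochs(1, n_epochs = 150, seed = 5)
  b1 <- wavelet_bicoherence(ep1, grid = bifreq_grid(1, 30))
  v1 <- b1$values
  peak <- v1$value[v1$f1 == 9 & v1$f2 == 6]
  expect_gte(peak, 0.8)
  # agreement with the direct-FFT bispectrum oracle on a stationary fixture
  eps <- triplet_epochs(1, n_epochs = 150, seed = 5, segment_s = "all")
  bs <- wavelet_bicoherence(eps, grid = bifreq_grid(1, 30))
  ps <- bs$values$value[bs$values$f1 == 9 & bs$values$f2 == 6]
  expect_lt(abs(ps - fourier_bicoherence(eps, 9, 6)), 0.1)
  ep0 <- triplet_epochs(0, n_epochs = 200, seed = 5)
  b0 <- wavelet_bicoherence(ep0, grid = bifreq_grid(1, 30))
  expect_lte(b0$values$value[b0$values$f1 == 9 & b0$values$f2 == 6], 0.15)
  expect_error(wavelet_bicoherence(raw_epochs(array(rnorm(512), c(1, 1, 512)), 256)),
               class = "eegbico_parameter_error")
})

test_that("white noise bicoherence stays small everywhere", {
  rec <- generate_background(1, 256, 102, slope = 0, seed = 14)
  b <- wavelet_bicoherence(make_epochs(rec), grid = bifreq_grid(1, 45))
  expect_lte(max(b$values$value), 0.2)
})

test_that("bicoherence is bounded and amplitude-invariant", {
  set.seed(101)
  for (i in 1:5) {
    arr <- array(rnorm(6 * 256), c(6, 1, 256))
    ep <- raw_epochs(arr, 128)
    g <- bifreq_grid(2, 30, 2, 4)
    b <- wavelet_bicoherence(ep, grid = g)
    expect_true(all(b$values$value >= 0 & b$values$value <= 1))
    eps <- ep; eps$epochs <- eps$epochs * 17
    bs <- wavelet_bicoherence(eps, grid = g)
    expect_equal(bs$values$value, b$values$value, tolerance = 1e-8)
  }
})

test_that("filtering respects trivial and surrogate thresholds", {
  ep <- triplet_epochs(1, n_epochs = 60, seed = 6)
  g <- bifreq_grid(1, 30)
  b <- wavelet_bicoherence(ep, grid = g)
  expect_equal(filter_bicoherence(b, 0)$values$value, b$values$value)
  expect_true(all(filter_bicoherence(b, 1)$values$value == 0))
  thr <- surrogate_threshold(ep, grid = g, n_surrogates = 10, seed = 2)
  fb <- filter_bicoherence(b, thr)
  surv <- fb$values[fb$values$value > 0, ]
  # the coupled cell survives and is the strongest survivor
  expect_true(any(surv$f1 == 9 & surv$f2 == 6))
  top <- surv[which.max(surv$value), ]
  expect_true(abs(top$f1 - 9) <= 1 && abs(top$f2 - 6) <= 1)
  # specificity: on a coupling-free 1/f background the filter passes only
  # about the nominal 5% of cells
  rec0 <- generate_background(1, 256, 32, slope = 1, seed = 16)
  ep0 <- make_epochs(rec0)
  b0 <- wavelet_bicoherence(ep0, grid = g)
  thr0 <- surrogate_threshold(ep0, grid = g, n_surrogates = 10, seed = 2)
  fb0 <- filter_bicoherence(b0, thr0)
  expect_lt(mean(fb0$values$value > 0), 0.15)
})

test_that("total band coupling sums squared bicoherence over the band pair", {
  g <- bifreq_grid(1, 45)
  pairs <- expand.grid(f1 = g$centers, f2 = g$centers)
  pairs <- pairs[pairs$f2 <= pairs$f1 & pairs$f1 + pairs$f2 <= 45, ]
  zero <- structure(
    list(values = tibble::tibble(f1 = pairs$f1, f2 = pairs$f2, value = 0),
         n_epochs = 10, channel = "ch01", session = NA, grid = g,
         value_type = "squared", filter = NULL),
    class = "eegbico_bicoherence")
  expect_equal(total_band_coupling(zero, "theta", "alpha"), 0)
  one <- zero
  one$values$value[one$values$f1 == 9 & one$values$f2 == 5] <- 0.6
  # stored values are already squared: summed as-is
  expect_equal(total_band_coupling(one, "theta", "alpha"), 0.6)
  expect_equal(total_band_coupling(one, "alpha", "theta"), 0.6)
  # magnitude-storage convention squares before summing
  one$value_type <- "magnitude"
  expect_equal(total_band_coupling(one, "theta", "alpha"), 0.36)
  # gamma-gamma has no cells under the 45 Hz cap -> NA sentinel
  expect_warning(res <- total_band_coupling(zero, "gamma", "gamma"))
  expect_true(is.na(res))
})

test_that("a theta-alpha triplet couples theta-alpha more than theta-beta", {
  ep <- triplet_epochs(1, n_epochs = 120, seed = 7)   # 6 + 9 Hz
  b <- wavelet_bicoherence(ep, grid = bifreq_grid(1, 45))
  expect_gt(total_band_coupling(b, "theta", "alpha"),
            total_band_coupling(b, "theta", "beta"))
})

test_that("band-pair summary covers all pairs with consistent cell counts", {
  ep <- triplet_epochs(1, n_epochs = 30, seed = 8)
  b <- wavelet_bicoherence(ep, grid = bifreq_grid(1, 45))
  tab <- band_pair_coupling(b)
  expect_equal(nrow(tab), 15)
  expect_true(is.na(tab$coupling[tab$band_j == "gamma" & tab$band_k == "gamma"]))
  expect_equal(sum(tab$n_cells), nrow(b$values))
})
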