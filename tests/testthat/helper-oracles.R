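# Independent oracles used to validate the package's estimators. These
# deliberately avoid the implementation paths they check.

# Direct FFT bispectrum estimate of squared bicoherence at (f1, f2) from an
# epoch set: one DFT bin per frequency, averaged over epochs only.
fourier_bicoherence <- function(ep, f1, f2, channel = 1) {
  L <- dim(ep$epochs)[3]
  fs <- ep$fs
  bin <- function(f) round(f * L / fs) + 1L
  b1 <- bin(f1); b2 <- bin(f2); b3 <- bin(f1 + f2)
  num <- 0i; d1 <- 0; d2 <- 0
  for (i in seq_len(dim(ep$epochs)[1])) {
    X <- fft(ep$epochs[i, channel, ])
    num <- num + X[b1] * X[b2] * Conj(X[b3])
    d1 <- d1 + Mod(X[b1] * X[b2])^2
    d2 <- d2 + Mod(X[b3])^2
  }
  Mod(num)^2 / (d1 * d2)
}

# Brute-force exact two-sided Mann-Whitney p by enumerating every assignment
# of the pooled observations to the two groups (no ties assumed).
enumerate_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - m * (m + 1) / 2
  }
  u_obs <- u_stat(seq_len(m))
  center <- m * length(y) / 2
  combos <- utils::combn(length(pooled), m)
  us <- apply(combos, 2, u_stat)
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}

# log-log periodogram slope of a single channel over [flo, fhi]
psd_slope <- function(x, fs, flo = 2, fhi = 40) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                          taper = 0, detrend = FALSE)
  sel <- sp$freq >= flo & sp$freq <= fhi
  unname(stats::coef(stats::lm(log10(sp$spec[sel]) ~ log10(sp$freq[sel])))[2])
}

# recording holding pure sinusoids: amps/freqs vectors, one channel
sinusoid_recording <- function(freqs, amps, fs = 256, duration = 10,
                               phases = 0) {
  tt <- (seq_len(fs * duration) - 1) / fs
  phases <- rep_len(phases, length(freqs))
  x <- rowSums(mapply(function(f, a, p) a * sin(2 * pi * f * tt + p),
                      freqs, amps, phases))
  recording(matrix(x, 1), fs = fs)
}

# epoch set from raw array without going through a recording
raw_epochs <- function(arr, fs, length_s = dim(arr)[3] / fs, overlap = 0) {
  structure(list(epochs = arr, fs = fs,
                 labels = sprintf("ch%02d", seq_len(dim(arr)[2])),
                 length_s = length_s, overlap = overlap,
                 session = NA_character_),
            class = "eegbico_epochs")
}

# the standard coupled-triplet fixture on a weak white background;
# segment_s = NULL keeps the 2 s phase segments, "all" makes the fixture
# stationary (one global phase draw)
triplet_epochs <- function(strength, n_epochs = 200, seed = 5,
                           f1 = 6, f2 = 9, amp = 3, segment_s = NULL) {
  dur <- (512 + (n_epochs - 1) * 128) / 256
  if (identical(segment_s, "all")) segment_s <- dur
  rec <- generate_background(1, 256, dur, slope = 0, rms = 1, seed = seed)
  rec <- inject_qpc_triplet(rec, f1, f2, strength = strength, amp = amp,
                            segment_s = segment_s %||% 2, seed = seed + 1)
  make_epochs(rec)
}
`%||%` <- function(a, b) if (is.null(a)) b else a
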