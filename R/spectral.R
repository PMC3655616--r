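# Morlet wavelet power spectra and canonical band powers.

#' Frequency grid
#'
#' @param lo,hi Grid limits in Hz (`lo < hi`).
#' @param step Grid step in Hz (default 0.5).
#' @return Numeric vector `lo, lo + step, ..., hi`.
#' @export
freq_grid <- function(lo = 1, hi = 45, step = 0.5) {
  assert_that(lo < hi && step > 0, "need lo < hi and step > 0")
  seq(lo, hi, by = step)
}

#' Canonical EEG frequency bands
#'
#' The five-band scheme used throughout: delta 1–4, theta 4–8, alpha 8–13,
#' beta 13–30, gamma 30–45 Hz. Bands share endpoints; grid points are
#' assigned half-open `[lo, hi)`, a shared endpoint belonging to the upper
#' band, except that gamma is closed `[30, 45]`.
#'
#' @return A tibble with columns `band` (ordered factor), `lo`, `hi`.
#' @export
canonical_bands <- function() {
  tibble(
    band = factor(c("delta", "theta", "alpha", "beta", "gamma"),
                  levels = c("delta", "theta", "alpha", "beta", "gamma")),
    lo = c(1, 4, 8, 13, 30),
    hi = c(4, 8, 13, 30, 45)
  )
}

#' Morlet wavelet power spectrum
#'
#' Estimates power per channel and frequency with a complex Morlet wavelet of
#' central angle frequency `omega` (default 6 cycles). Each epoch is
#' transformed in the frequency domain: for each analysis frequency `f` the
#' spectrum is weighted by the Morlet Gaussian (peak response normalised to 1
#' at `f`, negative frequencies zeroed) and inverted, giving an analytic
#' band signal whose squared magnitude, halved, estimates the local variance.
#' A pure sinusoid of amplitude `A` at a grid frequency therefore yields
#' power `A^2/2` (its variance) at that frequency. Power is averaged over
#' time within an epoch — excluding the cone of influence, i.e. `2 sigma_t`
#' of the wavelet at each edge, capped so that the central quarter of the
#' epoch is always retained — and then across epochs.
#'
#' @param ep An `eegbico_epochs` object from [make_epochs()].
#' @param grid Analysis frequencies from [freq_grid()].
#' @param omega Wavelet central angle frequency (cycles per envelope), >= 5
#'   for admissibility.
#' @param coi Exclude edge samples inside the cone of influence (default
#'   TRUE).
#' @return An `eegbico_power_spectrum`: list with `power` (channel x
#'   frequency matrix, same units as the squared input), `frequencies`,
#'   `labels`, `omega`, `session`.
#' @export
#' @examples
#' rec <- generate_background(1, 256, 10, seed = 1)
#' rec <- inject_oscillation(rec, 10, 2, rms = 20, seed = 2)
#' ps <- morlet_power(make_epochs(rec))
morlet_power <- function(ep, grid = freq_grid(1, 45, 0.5), omega = 6,
                         coi = TRUE) {
  fs <- ep$fs
  assert_that(max(grid) < fs / 2, "grid extends beyond Nyquist")
  assert_that(is_scalar_num(omega) && omega >= 5,
              "`omega` must be >= 5 (Morlet admissibility)")
  L <- dim(ep$epochs)[3]
  n_ch <- dim(ep$epochs)[2]
  n_ep <- dim(ep$epochs)[1]
  fk <- fft_freqs(L, fs)
  # Gaussian masks, one column per analysis frequency; analytic (f > 0 only),
  # peak-normalised so the response at the centre frequency is exactly 2
  # (recovering the analytic amplitude of a real sinusoid).
  masks <- vapply(grid, function(f) {
    s <- omega / (2 * pi * f)
    m <- 2 * exp(-(s * 2 * pi * fk - omega)^2 / 2)
    m[fk <= 0] <- 0
    m
  }, numeric(L))
  # retained-sample window per frequency (cone of influence)
  keep <- lapply(seq_along(grid), function(j) {
    if (!coi) return(seq_len(L))
    sigma_t <- omega / (2 * pi * grid[j])
    n_excl <- min(round(2 * sigma_t * fs), floor(0.375 * L))
    (n_excl + 1):(L - n_excl)
  })
  power <- matrix(0, n_ch, length(grid))
  for (ch in seq_len(n_ch)) {
    acc <- numeric(length(grid))
    for (i in seq_len(n_ep)) {
      X <- fft(ep$epochs[i, ch, ])
      W <- stats::mvfft(masks * X, inverse = TRUE) / L
      for (j in seq_along(grid)) {
        w <- W[keep[[j]], j]
        acc[j] <- acc[j] + mean(Mod(w)^2) / 2
      }
    }
    power[ch, ] <- acc / n_ep
  }
  structure(
    list(power = power, frequencies = grid, labels = ep$labels,
         omega = omega, fs = fs, session = ep$session),
    class = "eegbico_power_spectrum"
  )
}

#' @export
print.eegbico_power_spectrum <- function(x, ...) {
  cat(sprintf("<eegbico_power_spectrum> %d channels, %g-%g Hz (%d points), omega = %g\n",
              nrow(x$power), min(x$frequencies), max(x$frequencies),
              length(x$frequencies), x$omega))
  invisible(x)
}

#' Tidy a power spectrum into a long tibble
#'
#' @param x An `eegbico_power_spectrum`.
#' @param ... Unused.
#' @return A tibble with columns `session`, `channel`, `frequency`, `power`.
#' @method tidy eegbico_power_spectrum
#' @export
tidy.eegbico_power_spectrum <- function(x, ...) {
  tibble(
    session = x$session,
    channel = rep(x$labels, each = length(x$frequencies)),
    frequency = rep(x$frequencies, times = length(x$labels)),
    power = as.vector(t(x$power))
  )
}

#' @method autoplot eegbico_power_spectrum
#' @export
autoplot.eegbico_power_spectrum <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$frequency, .data$power,
                               colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(Power ~ (mu * V^2)),
                  colour = "Channel") +
    ggplot2::theme_minimal()
}

#' Absolute and relative band power
#'
#' Summarises a power spectrum over the canonical bands. `absolute` is the
#' mean spectral power over in-band grid points; `relative` is the in-band
#' power sum divided by the total over all listed bands, so relative values
#' sum to 1 per channel.
#'
#' @param spec An `eegbico_power_spectrum`.
#' @param bands Band scheme tibble from [canonical_bands()].
#' @return A tibble with columns `session`, `channel`, `band`, `absolute`,
#'   `relative`.
#' @export
band_power <- function(spec, bands = canonical_bands()) {
  f <- spec$frequencies
  idx <- band_membership(f, bands)
  empty <- vapply(idx, length, 0L) == 0
  if (any(empty)) {
    abort(paste("band(s) with no grid points:",
                paste(bands$band[empty], collapse = ", ")),
          class = "eegbico_config_error")
  }
  res <- purrr::map_dfr(seq_len(nrow(bands)), function(b) {
    cols <- idx[[b]]
    tibble(
      session = spec$session,
      channel = spec$labels,
      band = bands$band[b],
      absolute = rowMeans(spec$power[, cols, drop = FALSE]),
      insum = rowSums(spec$power[, cols, drop = FALSE])
    )
  })
  res |>
    group_by(.data$channel) |>
    mutate(relative = .data$insum / sum(.data$insum)) |>
    ungroup() |>
    select(-"insum") |>
    arrange(.data$channel, .data$band)
}

# indices of grid points per band: [lo, hi) except the last band, closed.
band_membership <- function(f, bands) {
  lapply(seq_len(nrow(bands)), function(b) {
    if (b == nrow(bands)) which(f >= bands$lo[b] & f <= bands$hi[b])
    else which(f >= bands$lo[b] & f < bands$hi[b])
  })
}

#' Percentage change between sessions
#'
#' The session-comparison change rate, `(after - before) / before * 100`,
#' computed per channel and band for both absolute and relative power. Cells
#' with a zero baseline are returned as `NA` and flagged in `undefined`
#' rather than dropped.
#'
#' @param after,before Band-power tibbles from [band_power()] with matching
#'   channels and bands.
#' @return A tibble with columns `channel`, `band`, `change_absolute`,
#'   `change_relative`, `undefined`.
#' @export
#' @examples
#' # a doubled spectrum gives +100% everywhere
change_rate <- function(after, before) {
  assert_that(setequal(after$channel, before$channel) &&
                setequal(after$band, before$band),
              "`after` and `before` must cover the same channels and bands")
  inner_join(after, before, by = c("channel", "band"),
             suffix = c("_after", "_before")) |>
    mutate(
      undefined = .data$absolute_before == 0 | .data$relative_before == 0,
      change_absolute = ifelse(.data$absolute_before == 0, NA_real_,
        100 * (.data$absolute_after - .data$absolute_before) / .data$absolute_before),
      change_relative = ifelse(.data$relative_before == 0, NA_real_,
        100 * (.data$relative_after - .data$relative_before) / .data$relative_before)
    ) |>
    select("channel", "band", "change_absolute", "change_relative", "undefined") |>
    arrange(.data$channel, .data$band)
}
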