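# Quadratic phase coupling via harmonic-wavelet bicoherence, surrogate-based
# significance filtering, and the band-pair total-coupling statistic.

#' Bifrequency analysis grid
#'
#' Centre frequencies `lo, lo + step, ..., hi` with an analysis bandwidth per
#' centre. Valid bifrequency pairs are restricted to the principal domain
#' `f_k <= f_j`, `f_j + f_k <= hi`.
#'
#' @param lo,hi Grid limits in Hz.
#' @param step Centre spacing in Hz (default 1).
#' @param bandwidth Analysis bandwidth per centre in Hz (default 2).
#' @return A list with fields `lo`, `hi`, `step`, `bandwidth`, `centers`.
#' @export
bifreq_grid <- function(lo = 1, hi = 45, step = 1, bandwidth = 2) {
  assert_that(lo < hi && step > 0 && bandwidth > 0,
              "need lo < hi, step > 0, bandwidth > 0")
  structure(list(lo = lo, hi = hi, step = step, bandwidth = bandwidth,
                 centers = seq(lo, hi, by = step)),
            class = "eegbico_bifreq_grid")
}

#' Harmonic-wavelet coefficients of one epoch
#'
#' The generalized harmonic wavelet has box-shaped spectral support, so its
#' coefficients are obtained exactly by frequency-domain masking: for each
#' centre frequency the DFT bins inside `[fc - bw/2, fc + bw/2)` are
#' retained (positive frequencies, doubled to form the analytic signal) and
#' inverted, giving one complex band-limited time series per centre.
#'
#' @param x Numeric vector, one epoch of one channel.
#' @param fs Sampling rate.
#' @param grid A [bifreq_grid()].
#' @return Complex matrix, `length(grid$centers)` rows by `length(x)`
#'   columns.
#' @export
harmonic_wavelet_coeffs <- function(x, fs, grid = bifreq_grid()) {
  L <- length(x)
  bw2 <- grid$bandwidth / 2
  assert_that(max(grid$centers) + bw2 <= fs / 2,
              "analysis band exceeds Nyquist")
  assert_that(L / fs >= 1 / grid$lo,
              "epoch must cover at least one cycle of the lowest centre frequency")
  fk <- fft_freqs(L, fs)
  X <- fft(x)
  out <- matrix(0i, length(grid$centers), L)
  for (j in seq_along(grid$centers)) {
    fc <- grid$centers[j]
    sel <- fk >= fc - bw2 & fk < fc + bw2 & fk > 0
    Xm <- rep(0i, L)
    Xm[sel] <- 2 * X[sel]
    out[j, ] <- fft(Xm, inverse = TRUE) / L
  }
  out
}

#' Wavelet bicoherence of one channel
#'
#' Squared-normalised bicoherence on the bifrequency grid from
#' harmonic-wavelet coefficients `W(f)`:
#' \deqn{b^2(f_j, f_k) = \frac{|\langle W(f_j) W(f_k) W^*(f_j + f_k)\rangle|^2}
#'   {\langle |W(f_j) W(f_k)|^2\rangle \, \langle |W(f_j+f_k)|^2\rangle}}
#' where the average pools time samples within epochs and across epochs. The
#' Cauchy–Schwarz inequality bounds the value in `[0, 1]`; values near 1 mean
#' the component at `f_j + f_k` keeps a fixed phase relation `phi_j + phi_k`
#' (quadratic phase coupling). Only the principal domain `f_k <= f_j`,
#' `f_j + f_k <= hi` is computed.
#'
#' @param ep An `eegbico_epochs` object (at least 2 epochs).
#' @param channel Channel label or index (default first channel).
#' @param grid A [bifreq_grid()].
#' @return An `eegbico_bicoherence` object: list with `values` (tibble
#'   `f1` = f_j, `f2` = f_k, `value`), `n_epochs`, `channel`, `session`,
#'   `grid`, `value_type = "squared"`, `filter` (NULL until
#'   [filter_bicoherence()]).
#' @export
#' @examples
#' rec <- generate_background(1, 256, 30, seed = 1)
#' rec <- inject_qpc_triplet(rec, 6, 9, strength = 1, amp = 20, seed = 2)
#' b <- wavelet_bicoherence(make_epochs(rec), grid = bifreq_grid(1, 20))
wavelet_bicoherence <- function(ep, channel = 1, grid = bifreq_grid()) {
  assert_that(n_epochs(ep) >= 2,
              "bicoherence needs at least 2 epochs (normalisation degenerate)")
  ch <- resolve_channels(list(labels = ep$labels), channel)[1]
  centers <- grid$centers
  pairs <- principal_pairs(grid)
  L <- dim(ep$epochs)[3]
  n_ep <- n_epochs(ep)
  jk_index <- match(pairs$f1 + pairs$f2, centers)
  j_index <- match(pairs$f1, centers)
  k_index <- match(pairs$f2, centers)
  num <- complex(length(j_index))
  d1 <- numeric(length(j_index))
  d2 <- numeric(length(j_index))
  chunk <- max(1L, 2e6 %/% L)
  for (start in seq(1L, n_ep, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_ep)
    W <- do.call(cbind, lapply(idx, function(i) {
      harmonic_wavelet_coeffs(ep$epochs[i, ch, ], ep$fs, grid)
    }))
    for (p in seq_along(j_index)) {
      w12 <- W[j_index[p], ] * W[k_index[p], ]
      w3 <- W[jk_index[p], ]
      num[p] <- num[p] + sum(w12 * Conj(w3))
      d1[p] <- d1[p] + sum(Mod(w12)^2)
      d2[p] <- d2[p] + sum(Mod(w3)^2)
    }
  }
  denom <- d1 * d2
  value <- ifelse(denom > 0, Mod(num)^2 / denom, 0)
  structure(
    list(values = tibble(f1 = pairs$f1, f2 = pairs$f2, value = value),
         n_epochs = n_ep, channel = ep$labels[ch], session = ep$session,
         grid = grid, value_type = "squared", filter = NULL),
    class = "eegbico_bicoherence"
  )
}

# principal-domain pairs (f2 <= f1, f1 + f2 <= hi); pairs whose sum exceeds
# the grid cap are excluded by construction.
principal_pairs <- function(grid) {
  g <- expand.grid(f1 = grid$centers, f2 = grid$centers)
  g[g$f2 <= g$f1 & (g$f1 + g$f2) <= grid$hi &
      !is.na(match(g$f1 + g$f2, grid$centers)), ]
}

#' @export
print.eegbico_bicoherence <- function(x, ...) {
  cat(sprintf("<eegbico_bicoherence> channel %s, %d bifrequency pairs, %d epochs\n",
              x$channel, nrow(x$values), x$n_epochs))
  if (!is.null(x$filter)) cat("  filtered:", x$filter$source, "\n")
  top <- x$values[which.max(x$values$value), ]
  cat(sprintf("  peak b^2 = %.3f at (%g, %g) Hz\n", top$value, top$f1, top$f2))
  invisible(x)
}

#' @method tidy eegbico_bicoherence
#' @export
tidy.eegbico_bicoherence <- function(x, ...) {
  mutate(x$values, channel = x$channel, session = x$session,
         .before = "f1")
}

#' @method glance eegbico_bicoherence
#' @export
glance.eegbico_bicoherence <- function(x, ...) {
  tibble(channel = x$channel, session = x$session, n_epochs = x$n_epochs,
         n_pairs = nrow(x$values), peak = max(x$values$value),
         filtered = !is.null(x$filter))
}

#' @method autoplot eegbico_bicoherence
#' @export
autoplot.eegbico_bicoherence <- function(object, ...) {
  ggplot2::ggplot(object$values,
                  ggplot2::aes(.data$f1, .data$f2, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(f[j] ~ (Hz)), y = expression(f[k] ~ (Hz)),
                  fill = expression(b^2)) +
    ggplot2::theme_minimal()
}

#' Surrogate-based significance thresholds
#'
#' Builds a null distribution for every bifrequency pair by phase
#' randomisation: the channel's continuous signal (reconstructed from the
#' epoch set) keeps its amplitude spectrum but receives fresh uniform
#' phases, destroying any phase coupling while preserving power, and is
#' re-epoched with the same length and overlap. Randomising the continuous
#' signal rather than each epoch keeps the dependence between overlapping
#' epochs, which the null distribution must reflect. The per-pair threshold
#' is the requested quantile of the surrogate bicoherence values.
#'
#' @param ep An `eegbico_epochs` object.
#' @param channel Channel label or index.
#' @param grid A [bifreq_grid()].
#' @param n_surrogates Number of surrogate realisations (default 40).
#' @param prob Quantile defining the threshold (default 0.95).
#' @param seed Integer seed.
#' @return A tibble with columns `f1`, `f2`, `threshold`.
#' @export
surrogate_threshold <- function(ep, channel = 1, grid = bifreq_grid(),
                                n_surrogates = 40, prob = 0.95, seed = 1) {
  assert_that(is_count(n_surrogates), "`n_surrogates` must be a positive integer")
  ch <- resolve_channels(list(labels = ep$labels), channel)[1]
  x <- epochs_to_signal(ep, ch)
  vals <- with_seed(seed, {
    vapply(seq_len(n_surrogates), function(s) {
      sx <- phase_randomize(x)
      sur <- make_epochs(recording(matrix(sx, 1), fs = ep$fs),
                         length_s = ep$length_s, overlap = ep$overlap)
      wavelet_bicoherence(sur, channel = 1, grid = grid)$values$value
    }, numeric(nrow(principal_pairs(grid))))
  })
  pairs <- principal_pairs(grid)
  tibble(f1 = pairs$f1, f2 = pairs$f2,
         threshold = apply(vals, 1, quantile, probs = prob, names = FALSE))
}

# rebuild one channel's continuous signal from a (possibly overlapping)
# epoch set; rejected-epoch gaps collapse by concatenation of steps
epochs_to_signal <- function(ep, ch) {
  L <- dim(ep$epochs)[3]
  step <- as.integer(round(L * (1 - ep$overlap)))
  n_ep <- n_epochs(ep)
  x <- numeric((n_ep - 1) * step + L)
  for (i in seq_len(n_ep)) {
    x[((i - 1) * step + 1):((i - 1) * step + L)] <- ep$epochs[i, ch, ]
  }
  x
}

# amplitude-preserving phase randomisation of a real signal
phase_randomize <- function(x) {
  n <- length(x)
  X <- fft(x)
  half <- (n - 2 + n %% 2) %/% 2            # positive non-Nyquist bins
  ph <- runif(half, 0, 2 * pi)
  Xn <- X
  Xn[2:(half + 1)] <- Mod(X[2:(half + 1)]) * exp(1i * ph)
  Xn[n:(n - half + 1)] <- Conj(Xn[2:(half + 1)])
  Re(fft(Xn, inverse = TRUE)) / n
}

#' Significance-filter a bicoherence matrix
#'
#' Sets bicoherence values at or below a threshold to zero, keeping the
#' rest — the "filtered" coupling estimate used for band-pair summaries. The
#' threshold may be a single number or a per-pair table from
#' [surrogate_threshold()]; its source is recorded in the result.
#'
#' @param bic An `eegbico_bicoherence`.
#' @param threshold Scalar in `[0, 1]`, or a tibble with columns `f1`, `f2`,
#'   `threshold`.
#' @return The filtered `eegbico_bicoherence`.
#' @export
filter_bicoherence <- function(bic, threshold) {
  if (is.numeric(threshold) && length(threshold) == 1) {
    assert_that(threshold >= 0 && threshold <= 1, "`threshold` must be in [0, 1]")
    thr <- rep(threshold, nrow(bic$values))
    src <- sprintf("fixed threshold %g", threshold)
  } else {
    assert_that(is.data.frame(threshold) &&
                  all(c("f1", "f2", "threshold") %in% names(threshold)),
                "`threshold` must be a scalar or an (f1, f2, threshold) table")
    m <- dplyr::left_join(bic$values, threshold, by = c("f1", "f2"))
    assert_that(!anyNA(m$threshold), "threshold table does not cover all pairs")
    thr <- m$threshold
    src <- "surrogate per-pair thresholds"
  }
  out <- bic
  out$values$value <- ifelse(bic$values$value > thr, bic$values$value, 0)
  out$filter <- list(source = src)
  out
}

#' Total coupling between two frequency bands
#'
#' The band-pair summary statistic: the sum of squared bicoherence over all
#' bifrequency cells with one frequency in each band, restricted to the
#' stored principal domain (cells with `f_j + f_k` above the grid cap do not
#' exist and are excluded; band pairs are treated symmetrically). With the
#' default `value_type = "squared"` storage the stored values are already
#' `b^2` and are summed as-is; with magnitude storage they are squared first
#' (`square_values = TRUE` forces the latter behaviour).
#'
#' @param bic An `eegbico_bicoherence`, optionally filtered.
#' @param band_j,band_k Band names from `bands`.
#' @param bands Band scheme from [canonical_bands()].
#' @param square_values Square stored values before summing; defaults to
#'   `TRUE` only when the object stores magnitudes.
#' @return A single number, or `NA` (with a warning) when the band pair has
#'   no valid cells under the grid cap (e.g. gamma–gamma with a 45 Hz cap).
#' @export
#' @examples
#' # see band_pair_coupling() for the all-pairs table
total_band_coupling <- function(bic, band_j, band_k,
                                bands = canonical_bands(),
                                square_values = NULL) {
  square_values <- square_values %||% (bic$value_type != "squared")
  bj <- bands[match(band_j, as.character(bands$band)), ]
  bk <- bands[match(band_k, as.character(bands$band)), ]
  assert_that(nrow(bj) == 1 && !anyNA(bj$lo) && nrow(bk) == 1 && !anyNA(bk$lo),
              "unknown band name")
  v <- bic$values
  in_band <- function(f, b) {
    if (as.character(b$band) == as.character(tail(bands$band, 1))) {
      f >= b$lo & f <= b$hi
    } else f >= b$lo & f < b$hi
  }
  sel <- (in_band(v$f1, bj) & in_band(v$f2, bk)) |
         (in_band(v$f1, bk) & in_band(v$f2, bj))
  if (!any(sel)) {
    warn(sprintf("band pair (%s, %s): no valid bifrequency cells under the %g Hz cap",
                 band_j, band_k, bic$grid$hi))
    return(NA_real_)
  }
  x <- v$value[sel]
  sum(if (square_values) x^2 else x)
}

#' Band-pair coupling summary table
#'
#' [total_band_coupling()] evaluated for every unordered band pair.
#'
#' @inheritParams total_band_coupling
#' @return A tibble with columns `band_j`, `band_k`, `coupling`, `n_cells`.
#' @export
band_pair_coupling <- function(bic, bands = canonical_bands(),
                               square_values = NULL) {
  nm <- as.character(bands$band)
  combos <- expand.grid(j = seq_along(nm), k = seq_along(nm))
  combos <- combos[combos$k <= combos$j, ]
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    bj <- nm[combos$j[i]]; bk <- nm[combos$k[i]]
    b <- suppressWarnings(
      total_band_coupling(bic, bj, bk, bands, square_values))
    v <- bic$values
    in_b <- function(f, b_) {
      row <- bands[match(b_, nm), ]
      if (b_ == tail(nm, 1)) f >= row$lo & f <= row$hi else f >= row$lo & f < row$hi
    }
    n_cells <- sum((in_b(v$f1, bj) & in_b(v$f2, bk)) |
                   (in_b(v$f1, bk) & in_b(v$f2, bj)))
    tibble(band_j = bj, band_k = bk, coupling = b, n_cells = n_cells)
  })
}
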