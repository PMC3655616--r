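# Synthetic EEG and behavioural-sequence generators. Every generator is a
# pure function of its arguments including the seed, so downstream stages can
# be tested against known ground truth.

#' Generate 1/f background activity
#'
#' Synthesises `n_channels` of coloured noise whose power spectral density
#' falls off as `1/f^slope`, by spectral shaping: white Gaussian noise is
#' transformed to the frequency domain, its amplitudes scaled by
#' `f^(-slope/2)` (DC removed), and transformed back. This gives exact slope
#' control. Each channel gets an independent realisation.
#'
#' @param n_channels Number of channels.
#' @param fs Sampling rate (samples/s).
#' @param duration Length in seconds; `duration * fs` must be an integer.
#' @param slope The 1/f exponent (0 = white noise, 1 = pink).
#' @param rms Target root-mean-square amplitude per channel (microvolts).
#' @param labels,session Passed to [recording()].
#' @param seed Integer seed; identical seeds give identical samples.
#' @return An [recording()].
#' @export
#' @examples
#' bg <- generate_background(2, fs = 256, duration = 4, slope = 1, seed = 1)
generate_background <- function(n_channels, fs, duration, slope = 1, rms = 10,
                                labels = NULL, session = NA_character_,
                                seed = 1) {
  assert_that(is_count(n_channels), "`n_channels` must be a positive integer")
  assert_that(is_scalar_num(fs) && fs > 0, "`fs` must be positive")
  assert_that(is_scalar_num(duration) && duration > 0, "`duration` must be positive")
  n <- duration * fs
  assert_that(abs(n - round(n)) < 1e-9, "`duration * fs` must be an integer sample count")
  assert_that(is_scalar_num(slope) && slope >= 0, "`slope` must be >= 0")
  n <- as.integer(round(n))
  f <- abs(fft_freqs(n, fs))
  g <- ifelse(f > 0, f^(-slope / 2), 0)     # zero out DC
  data <- with_seed(seed, {
    t(vapply(seq_len(n_channels), function(ch) {
      x <- rnorm(n)
      y <- Re(fft(fft(x) * g, inverse = TRUE)) / n
      y / sqrt(mean(y^2)) * rms
    }, numeric(n)))
  })
  recording(data, fs = fs, labels = labels, session = session)
}

#' Add a band-limited oscillatory component
#'
#' Adds narrow-band filtered Gaussian noise of a requested RMS amplitude to a
#' subset of channels, leaving the other channels bit-identical. Band-limited
#' noise (rather than a pure sinusoid) gives realistic non-sinusoidal band
#' power.
#'
#' @param rec An [recording()].
#' @param center Centre frequency (Hz).
#' @param bandwidth Full bandwidth (Hz); the component occupies
#'   `center +/- bandwidth/2`, which must lie inside `(0, fs/2)`.
#' @param rms RMS amplitude of the added component (microvolts); `rms = 0`
#'   returns the input unchanged.
#' @param channels Channel labels or indices to modify (default: all).
#' @param seed Integer seed.
#' @return A new [recording()] with the component added.
#' @export
inject_oscillation <- function(rec, center, bandwidth, rms,
                               channels = NULL, seed = 1) {
  lo <- center - bandwidth / 2
  hi <- center + bandwidth / 2
  assert_that(lo > 0 && hi < rec$fs / 2,
              sprintf("band [%g, %g] Hz must lie inside (0, %g) Hz", lo, hi, rec$fs / 2))
  assert_that(is_scalar_num(rms) && rms >= 0, "`rms` must be >= 0")
  if (rms == 0) return(rec)
  chans <- resolve_channels(rec, channels)
  bf <- signal::butter(4, c(lo, hi) / (rec$fs / 2), type = "pass")
  n <- n_samples(rec)
  out <- rec
  add <- with_seed(seed, {
    lapply(chans, function(ch) {
      z <- signal::filtfilt(bf, rnorm(n))
      z / sqrt(mean(z^2)) * rms
    })
  })
  for (i in seq_along(chans)) {
    out$data[chans[i], ] <- out$data[chans[i], ] + add[[i]]
  }
  out
}

#' Add a quadratically phase-coupled frequency triplet
#'
#' Adds three sinusoids at `f1`, `f2` and `f1 + f2`. Time is divided into
#' consecutive segments (default 2 s, matching the analysis epoch length);
#' within each segment the phases of the `f1` and `f2` components are drawn
#' uniformly, and the phase of the `f1 + f2` component equals their sum
#' (quadratic phase coupling) on a fraction `strength` of segments, chosen at
#' random, and is drawn independently on the rest. With constant amplitudes
#' the asymptotic squared bicoherence at `(f1, f2)` is approximately
#' `strength^2`, so `strength = 1` gives full coupling and `strength = 0` the
#' independent-phase null.
#'
#' @param rec An [recording()].
#' @param f1,f2 Component frequencies (Hz); `f1 + f2` must stay below
#'   Nyquist.
#' @param strength Fraction of segments with locked phase, in `[0, 1]`.
#' @param amp Amplitude of each sinusoid (microvolts); `amp = 0` is a no-op.
#' @param channels Channels to modify (default: all); each channel gets
#'   independent phase draws.
#' @param segment_s Segment length in seconds.
#' @param edge_taper Raised-cosine amplitude ramp (s) applied at each
#'   segment edge of the added waveform, suppressing the broadband leakage
#'   the per-segment phase jumps would otherwise create (0 disables).
#' @param seed Integer seed.
#' @return A new [recording()].
#' @export
inject_qpc_triplet <- function(rec, f1, f2, strength, amp,
                               channels = NULL, segment_s = 2,
                               edge_taper = 0.1, seed = 1) {
  assert_that(f1 > 0 && f2 > 0 && f1 + f2 < rec$fs / 2,
              "f1, f2 and f1 + f2 must lie inside (0, Nyquist)")
  assert_that(is_scalar_num(strength) && strength >= 0 && strength <= 1,
              "`strength` must be in [0, 1]")
  assert_that(is_scalar_num(amp) && amp >= 0, "`amp` must be >= 0")
  if (amp == 0) return(rec)
  chans <- resolve_channels(rec, channels)
  n <- n_samples(rec)
  seg_len <- as.integer(round(segment_s * rec$fs))
  n_seg <- ceiling(n / seg_len)
  seg_id <- rep(seq_len(n_seg), each = seg_len)[seq_len(n)]
  tt <- (seq_len(n) - 1) / rec$fs
  f3 <- f1 + f2
  # per-sample amplitude window: raised-cosine ramps at segment edges
  win <- rep(1, n)
  nt <- round(edge_taper * rec$fs)
  if (nt > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nt) / nt))
    seg_win <- rep(1, seg_len)
    seg_win[seq_len(nt)] <- ramp
    seg_win[seg_len + 1 - seq_len(nt)] <- ramp
    win <- rep(seg_win, n_seg)[seq_len(n)]
  }
  out <- rec
  with_seed(seed, {
    for (ch in chans) {
      phi1 <- runif(n_seg, 0, 2 * pi)
      phi2 <- runif(n_seg, 0, 2 * pi)
      phi3 <- runif(n_seg, 0, 2 * pi)          # independent by default
      n_coupled <- round(strength * n_seg)
      if (n_coupled > 0) {
        locked <- sample.int(n_seg, n_coupled)
        phi3[locked] <- phi1[locked] + phi2[locked]
      }
      x <- amp * win * (cos(2 * pi * f1 * tt + phi1[seg_id]) +
                        cos(2 * pi * f2 * tt + phi2[seg_id]) +
                        cos(2 * pi * f3 * tt + phi3[seg_id]))
      out$data[ch, ] <- out$data[ch, ] + x
    }
  })
  out
}

resolve_channels <- function(rec, channels) {
  if (is.null(channels)) return(seq_along(rec$labels))
  if (is.character(channels)) {
    idx <- match(channels, rec$labels)
    assert_that(!anyNA(idx), "unknown channel label")
    idx
  } else {
    assert_that(all(channels >= 1 & channels <= length(rec$labels)),
                "channel index out of range")
    as.integer(channels)
  }
}

#' Compose a full synthetic session
#'
#' Convenience wrapper building a recording from a 1/f background plus any
#' number of band-limited components and phase-coupled triplets, with all
#' randomness derived from one root seed.
#'
#' @param n_channels,fs,duration,slope,rms,labels,session As in
#'   [generate_background()].
#' @param components List of `list(center, bandwidth, rms, channels)` entries
#'   passed to [inject_oscillation()].
#' @param triplets List of `list(f1, f2, strength, amp, channels)` entries
#'   passed to [inject_qpc_triplet()].
#' @param seed Root seed.
#' @return An [recording()].
#' @export
synth_session <- function(n_channels = 14, fs = 256, duration = 60,
                          slope = 1, rms = 10,
                          components = list(), triplets = list(),
                          labels = NULL, session = NA_character_, seed = 1) {
  n_sub <- 1 + length(components) + length(triplets)
  seeds <- with_seed(seed, sample.int(2^30, n_sub))
  rec <- generate_background(n_channels, fs, duration, slope = slope, rms = rms,
                             labels = labels, session = session, seed = seeds[1])
  k <- 1
  for (cmp in components) {
    k <- k + 1
    rec <- inject_oscillation(rec, cmp$center, cmp$bandwidth, cmp$rms,
                              channels = cmp$channels, seed = seeds[k])
  }
  for (tr in triplets) {
    k <- k + 1
    rec <- inject_qpc_triplet(rec, tr$f1, tr$f2, tr$strength, tr$amp,
                              channels = tr$channels, seed = seeds[k])
  }
  rec
}

#' Simulated von Frey responder
#'
#' A responder model for up-down simulations: the probability of a positive
#' (withdrawal) response is logistic in `log10(force)` around the true
#' threshold. `slope = Inf` gives the deterministic step responder
#' (positive whenever force >= threshold).
#'
#' @param true_threshold True 50% threshold in grams.
#' @param slope Logistic steepness per log10-gram; `Inf` for deterministic.
#' @return An object of class `eegbico_responder`.
#' @export
responder <- function(true_threshold, slope = Inf) {
  assert_that(is_scalar_num(true_threshold) && true_threshold > 0,
              "`true_threshold` must be > 0")
  assert_that(is.numeric(slope) && length(slope) == 1 && slope > 0,
              "`slope` must be > 0 (possibly Inf)")
  structure(list(true_threshold = true_threshold, slope = slope),
            class = "eegbico_responder")
}

respond_prob <- function(resp, force) {
  if (is.infinite(resp$slope)) as.numeric(force >= resp$true_threshold)
  else plogis(resp$slope * (log10(force) - log10(resp$true_threshold)))
}

#' Simulate an up-down von Frey testing sequence
#'
#' Runs the adaptive staircase: after a positive response the next weaker
#' filament is applied, after a negative response the next stronger one, and
#' testing stops six stimuli after the first change in response. At the
#' ladder boundaries the boundary filament is repeated; if the boundary
#' filament is presented `boundary_repeats` times in a row before any change
#' in response has occurred, the sequence terminates as saturated (the
#' subject's threshold lies beyond the ladder).
#'
#' @param resp An [responder()].
#' @param filaments Strictly increasing vector of filament forces in grams
#'   (default the standard eight-filament ladder, see [von_frey_forces()]).
#' @param start_force Starting force, must be one of `filaments`.
#' @param max_post_change Stimuli delivered after the first response change
#'   (default 6).
#' @param boundary_repeats Consecutive pre-change boundary presentations that
#'   trigger saturated termination.
#' @param seed Integer seed (used only for stochastic responders).
#' @return An object of class `eegbico_updown`: a list with a `trials` tibble
#'   (`trial`, `force_g`, `response`), `first_change_index`, `terminated` and
#'   `saturated` (`NA`, `"low"` or `"high"`).
#' @export
#' @examples
#' simulate_updown(responder(2.5), start_force = 2.00)
simulate_updown <- function(resp, filaments = von_frey_forces(),
                            start_force = 2.00, max_post_change = 6,
                            boundary_repeats = 4, seed = 1) {
  assert_that(length(filaments) >= 1 && all(diff(filaments) > 0),
              "`filaments` must be a non-empty strictly increasing ladder")
  idx <- match(start_force, filaments)
  assert_that(!is.na(idx), "`start_force` must be one of the filament forces")
  forces <- numeric(0)
  responses <- integer(0)
  first_change <- NA_integer_
  boundary_run <- 0L
  saturated <- NA_character_
  with_seed(seed, {
    repeat {
      force <- filaments[idx]
      r <- as.integer(runif(1) < respond_prob(resp, force))
      forces <- c(forces, force)
      responses <- c(responses, r)
      k <- length(responses)
      if (is.na(first_change) && k >= 2 && responses[k] != responses[k - 1]) {
        first_change <- k
      }
      if (!is.na(first_change) && k >= first_change + max_post_change) break
      at_boundary <- (r == 1 && idx == 1) || (r == 0 && idx == length(filaments))
      if (is.na(first_change) && at_boundary) {
        boundary_run <- boundary_run + 1L
        if (boundary_run >= boundary_repeats) {
          saturated <- if (r == 1) "low" else "high"
          break
        }
      } else boundary_run <- 0L
      idx <- if (r == 1) max(idx - 1L, 1L) else min(idx + 1L, length(filaments))
    }
  })
  new_updown(forces, responses, first_change = first_change,
             saturated = saturated)
}

# Constructor shared with read_updown(): recomputes bookkeeping from the raw
# (force, response) pairs when not supplied.
new_updown <- function(forces, responses, first_change = NULL, saturated = NULL) {
  stopifnot(length(forces) == length(responses))
  if (is.null(first_change)) {
    ch <- which(diff(responses) != 0)
    first_change <- if (length(ch)) ch[1] + 1L else NA_integer_
  }
  if (is.null(saturated)) {
    saturated <- if (is.na(first_change)) {
      if (all(responses == 1)) "low" else "high"
    } else NA_character_
  }
  structure(
    list(trials = tibble(trial = seq_along(forces), force_g = forces,
                         response = as.integer(responses)),
         first_change_index = first_change,
         terminated = TRUE,
         saturated = saturated),
    class = "eegbico_updown"
  )
}

#' @export
print.eegbico_updown <- function(x, ...) {
  pat <- paste(ifelse(x$trials$response == 1, "X", "O"), collapse = "")
  cat(sprintf("<eegbico_updown> %d trials, pattern %s\n", nrow(x$trials), pat))
  if (!is.na(x$saturated)) cat("  saturated:", x$saturated, "\n")
  invisible(x)
}

#' @method tidy eegbico_updown
#' @export
tidy.eegbico_updown <- function(x, ...) x$trials

#' Synthetic three-session study
#'
#' Builds the standard desk-scale validation study: one group of subjects
#' recorded in three sessions — a baseline (`before`), a session with the
#' oscillatory signature of postincisional pain (`after`: the dominant delta
#' component strongly attenuated while theta/alpha/beta power rises through
#' phase-coupled triplets whose components and sum frequencies fall in those
#' bands), and a treatment session (`ea`) in which the beta-involving
#' coupled triplets are absent, withdrawing the beta excess and the
#' beta-to-low-frequency coupling. The delta attenuation is sized so the
#' total (constant-Q-weighted) spectral sum is approximately conserved
#' between `before` and `after`, leaving gamma relative power neutral.
#' Between-subject variability enters as a lognormal amplitude factor per
#' subject and band (15% scale, a stable trait across sessions) plus an
#' independent 10% per-session factor.
#'
#' @param n_subjects Number of subjects per session (default 8).
#' @param n_channels Channels per recording (default 12, labelled from the
#'   scalp rows of [rat_montage()]).
#' @param fs Sampling rate (default 256).
#' @param duration Recording length per session in seconds (default 40).
#' @param coupling_strength Phase-locking fraction of the injected triplets
#'   (default 1).
#' @param seed Root seed.
#' @return A named list of sessions (`before`, `after`, `ea`), each a list
#'   of `n_subjects` recordings — the shape [run_pipeline()] expects.
#' @export
synth_study <- function(n_subjects = 8, n_channels = 12, fs = 256,
                        duration = 40, coupling_strength = 1, seed = 1) {
  labels <- utils::head(rat_montage()$label, n_channels)
  base_rms <- c(delta = 14, theta = 4, alpha = 4, beta = 4, gamma = 3)
  centers <- c(delta = 2.5, theta = 7, alpha = 11, beta = 25, gamma = 37)
  widths <- c(delta = 2, theta = 2, alpha = 3, beta = 8, gamma = 10)
  # coupled triplets for `after`, placed in analysis bands clear of the band
  # components so each triplet sinusoid keeps a usable signal-to-noise
  # ratio: (9,5) couples alpha-theta, (14,5) beta-theta, (17,9) beta-alpha
  triplets_after <- list(
    list(f1 = 9, f2 = 5),
    list(f1 = 14, f2 = 5),
    list(f1 = 17, f2 = 9)
  )
  master <- with_seed(seed, {
    list(trait = matrix(exp(rnorm(n_subjects * 5, 0, 0.15)), n_subjects, 5,
                        dimnames = list(NULL, names(base_rms))),
         seeds = matrix(sample.int(2^30, n_subjects * 3 * 7),
                        nrow = n_subjects))
  })
  sessions <- c("before", "after", "ea")
  out <- lapply(seq_along(sessions), function(si) {
    sess <- sessions[si]
    lapply(seq_len(n_subjects), function(subj) {
      sd_row <- master$seeds[subj, ((si - 1) * 7 + 1):(si * 7)]
      rms <- base_rms * master$trait[subj, ]
      if (sess %in% c("after", "ea")) rms["delta"] <- rms["delta"] * 5 / 14
      sess_jit <- with_seed(sd_row[1], exp(rnorm(5, 0, 0.10)))
      rms <- rms * sess_jit
      comps <- lapply(names(base_rms), function(b) {
        list(center = centers[[b]], bandwidth = widths[[b]], rms = rms[[b]],
             channels = NULL)
      })
      trips <- if (sess == "after") {
        lapply(triplets_after, function(tr) {
          list(f1 = tr$f1, f2 = tr$f2, strength = coupling_strength,
               amp = 3, channels = NULL)
        })
      } else if (sess == "ea") {
        list(list(f1 = 9, f2 = 5, strength = coupling_strength, amp = 3,
                  channels = NULL))
      } else list()
      synth_session(n_channels = n_channels, fs = fs, duration = duration,
                    slope = 1, rms = 10, components = comps,
                    triplets = trips, labels = labels, session = sess,
                    seed = sd_row[2])
    })
  })
  setNames(out, sessions)
}
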