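# The up-down 50% withdrawal-threshold estimator.
#
# The estimate is 10^(Xf + k * delta) / 10^4 grams, where Xf is the log10 of
# the last filament force expressed in 0.1 mg units (log10(10^4 * grams)),
# delta is the mean log10 spacing of the filament ladder, and k is a
# correction read from the pattern of positive/negative responses. The
# packaged k table is tabulated by maximum likelihood under a normal
# psychometric function with sigma = delta (the construction behind the
# classical up-down tables); it is derived data, not transcribed from any
# publication.

#' The standard eight-filament von Frey ladder
#'
#' @return Bending forces in grams: 0.41, 0.70, 1.20, 2.00, 3.63, 5.50,
#'   8.50, 15.10.
#' @export
von_frey_forces <- function() c(0.41, 0.70, 1.20, 2.00, 3.63, 5.50, 8.50, 15.10)

#' Construct a filament ladder
#'
#' @param forces Strictly increasing bending forces in grams.
#' @return An `eegbico_ladder`: list with `forces`, `log_forces` (log10
#'   grams) and `delta`, the mean log10 spacing.
#' @export
#' @examples
#' filament_ladder()$delta      # 0.224 for the standard ladder
filament_ladder <- function(forces = von_frey_forces()) {
  assert_that(length(forces) >= 2 && all(diff(forces) > 0),
              "`forces` must be strictly increasing with at least 2 filaments")
  structure(list(forces = forces, log_forces = log10(forces),
                 delta = mean(diff(log10(forces)))),
            class = "eegbico_ladder")
}

#' Mean log10 spacing of a ladder
#'
#' @param ladder An `eegbico_ladder` or numeric force vector.
#' @return Mean of successive `log10` force differences.
#' @export
mean_log_interval <- function(ladder) {
  if (is.numeric(ladder)) ladder <- filament_ladder(ladder)
  ladder$delta
}

#' The k correction table
#'
#' Reads the packaged pattern-to-k table covering every terminal response
#' pattern reachable under the termination rule (a run of identical
#' responses, the first change, then six further stimuli) on an interior
#' stretch of the ladder. Patterns are strings of `O` (negative) and `X`
#' (positive withdrawal). The values are maximum-likelihood corrections
#' computed by [make_k_table()]; see that function for the model.
#'
#' @return A tibble with columns `pattern` and `k`.
#' @export
k_table <- function() {
  path <- system.file("extdata", "k_table.csv", package = "eegbico")
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Maximum-likelihood k for a response pattern
#'
#' Reconstructs the stimulus levels implied by the up-down rule on an
#' interior stretch of the ladder (step down after `X`, up after `O`),
#' expresses them in units of the ladder spacing relative to the last level,
#' and maximises the likelihood of the responses under
#' `P(X at level m) = pnorm(m - mu)` (normal psychometric function with
#' sigma equal to one ladder step). The correction is `k = mu_hat`, the
#' estimated 50% point in step units above the last filament.
#'
#' @param responses Integer/logical vector of responses (1 = positive `X`),
#'   or a pattern string such as `"OOXOXXOX"`.
#' @return The k value (scalar).
#' @export
dixon_k <- function(responses) {
  r <- parse_pattern(responses)
  assert_that(length(unique(r)) == 2, "pattern must contain both responses")
  m <- numeric(length(r))
  for (i in seq_along(r)[-1]) m[i] <- m[i - 1] + if (r[i - 1] == 1) -1 else 1
  m <- m - m[length(m)]
  nll <- function(mu) {
    p <- pnorm(m - mu)
    -sum(ifelse(r == 1, log(pmax(p, 1e-300)), log(pmax(1 - p, 1e-300))))
  }
  optimize(nll, c(-12, 12))$minimum
}

parse_pattern <- function(responses) {
  if (is.character(responses) && length(responses) == 1) {
    as.integer(strsplit(responses, "")[[1]] == "X")
  } else as.integer(responses)
}

#' Tabulate k for all reachable terminal patterns
#'
#' Enumerates every response pattern reachable under the termination rule —
#' a prefix run of 1 to `max_prefix` identical responses, the first change,
#' then `n_post` free responses — and computes each pattern's
#' maximum-likelihood k with [dixon_k()]. This is how the packaged
#' `k_table.csv` is generated.
#'
#' @param max_prefix Longest prefix run tabulated (default 7, one less than
#'   the standard ladder length).
#' @param n_post Stimuli after the first change (default 6).
#' @return A tibble with columns `pattern`, `k`.
#' @export
make_k_table <- function(max_prefix = 7, n_post = 6) {
  rows <- list()
  for (first in 0:1) {
    for (run in seq_len(max_prefix)) {
      tails <- expand.grid(rep(list(0:1), n_post))
      for (t_i in seq_len(nrow(tails))) {
        r <- c(rep(first, run), 1 - first, as.integer(tails[t_i, ]))
        pat <- paste(ifelse(r == 1, "X", "O"), collapse = "")
        rows[[pat]] <- tibble(pattern = pat, k = dixon_k(r))
      }
    }
  }
  bind_rows(rows)
}

#' Evaluate the threshold formula directly
#'
#' `10^(Xf + k * delta) / 10^4` with `Xf = log10(10^4 * force_g)`; at
#' `k = 0` this returns the last filament's force exactly.
#'
#' @param last_force_g Last filament force in grams.
#' @param k Pattern correction.
#' @param delta Mean log10 ladder spacing.
#' @return Threshold in grams.
#' @export
pwt_formula <- function(last_force_g, k, delta) {
  xf <- log10(1e4 * last_force_g)
  10^(xf + k * delta) / 1e4
}

#' 50% withdrawal threshold from an up-down sequence
#'
#' Applies the pattern correction and the threshold formula to a terminated
#' up-down sequence. Saturated sequences (the subject never changed
#' response before repeated boundary presentations) are reported as censored
#' bounds at the ladder limits, not point estimates. Interior sequences are
#' looked up in the k table by their full response pattern; sequences that
#' touched a ladder boundary after the first change (so the tabulated
#' interior levels do not match the forces actually delivered) fall back to
#' direct maximum-likelihood estimation on the delivered forces. An
#' interior pattern absent from the table is an error, never a silent
#' default.
#'
#' @param seq An `eegbico_updown` sequence.
#' @param ladder An `eegbico_ladder` (default the standard eight filaments).
#' @param ktab k table from [k_table()] / [make_k_table()].
#' @param k Optional explicit k, bypassing the table.
#' @return A one-row tibble: `threshold_g`, `censored` (`"none"`, `"low"`,
#'   `"high"`), `k`, `pattern`, `method`.
#' @export
#' @examples
#' s <- simulate_updown(responder(2.5), seed = 7)
#' pwt50(s)
pwt50 <- function(seq, ladder = filament_ladder(), ktab = k_table(), k = NULL) {
  forces <- seq$trials$force_g
  responses <- seq$trials$response
  pat <- paste(ifelse(responses == 1, "X", "O"), collapse = "")
  if (!is.na(seq$saturated)) {
    bound <- if (seq$saturated == "low") min(ladder$forces) else max(ladder$forces)
    return(tibble(threshold_g = bound, censored = seq$saturated,
                  k = NA_real_, pattern = pat, method = "censored"))
  }
  last <- forces[length(forces)]
  assert_that(last %in% ladder$forces, "last force is not on the ladder")
  if (is.null(k)) {
    if (interior_consistent(forces, responses, ladder)) {
      hit <- match(pat, ktab$pattern)
      if (is.na(hit)) {
        abort(sprintf("response pattern '%s' not in the k table", pat),
              class = "eegbico_pattern_error")
      }
      k <- ktab$k[hit]
      method <- "table"
    } else {
      k <- ml_k_from_forces(forces, responses, ladder$delta)
      method <- "ml_direct"
    }
  } else method <- "explicit"
  est <- pwt_formula(last, k, ladder$delta)
  censored <- "none"
  if (est < min(ladder$forces)) { est <- min(ladder$forces); censored <- "low" }
  if (est > max(ladder$forces)) { est <- max(ladder$forces); censored <- "high" }
  tibble(threshold_g = est, censored = censored, k = k, pattern = pat,
         method = method)
}

# do the delivered forces match the interior up-down reconstruction?
interior_consistent <- function(forces, responses, ladder) {
  idx <- match(forces, ladder$forces)
  if (anyNA(idx)) return(FALSE)
  for (i in seq_along(idx)[-1]) {
    want <- idx[i - 1] + if (responses[i - 1] == 1) -1L else 1L
    if (want < 1 || want > length(ladder$forces) || idx[i] != want) return(FALSE)
  }
  TRUE
}

# ML estimate of k on the delivered forces (log10 scale, sigma = delta)
ml_k_from_forces <- function(forces, responses, delta) {
  x <- log10(forces)
  xf <- x[length(x)]
  nll <- function(mu) {
    p <- pnorm((x - mu) / delta)
    -sum(ifelse(responses == 1, log(pmax(p, 1e-300)),
                log(pmax(1 - p, 1e-300))))
  }
  mu <- optimize(nll, xf + c(-12, 12) * delta)$minimum
  (mu - xf) / delta
}

#' Bias and precision of the up-down estimator
#'
#' Simulates repeated up-down sequences for a grid of true thresholds and
#' summarises the resulting estimates.
#'
#' @param true_thresholds Vector of true thresholds in grams.
#' @param ladder An `eegbico_ladder`.
#' @param n_reps Replicates per threshold.
#' @param slope Responder steepness (see [responder()]); `Inf` =
#'   deterministic.
#' @param start_force Starting filament force.
#' @param seed Integer root seed.
#' @return A tibble with one row per true threshold: `true_threshold`,
#'   `n`, `mean_est`, `sd_est`, `censored_rate`.
#' @export
estimator_study <- function(true_thresholds, ladder = filament_ladder(),
                            n_reps = 20, slope = Inf, start_force = 2.00,
                            seed = 1) {
  assert_that(is_count(n_reps), "`n_reps` must be a positive integer")
  ktab <- k_table()
  seeds <- with_seed(seed, sample.int(2^30, length(true_thresholds) * n_reps))
  purrr::map_dfr(seq_along(true_thresholds), function(i) {
    thr <- true_thresholds[i]
    ests <- purrr::map_dfr(seq_len(n_reps), function(r) {
      s <- simulate_updown(responder(thr, slope), filaments = ladder$forces,
                           start_force = start_force,
                           seed = seeds[(i - 1) * n_reps + r])
      pwt50(s, ladder, ktab)
    })
    tibble(true_threshold = thr, n = n_reps,
           mean_est = mean(ests$threshold_g), sd_est = sd(ests$threshold_g),
           censored_rate = mean(ests$censored != "none"))
  })
}
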