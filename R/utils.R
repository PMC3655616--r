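# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic code in the package funnels through
# this so that generators are pure functions of (spec, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg, class = "eegbico_parameter_error")
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x > 0 && x == round(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# Frequencies (Hz) of the positive half of an n-point DFT at sampling rate fs,
# plus the full signed frequency vector used for masking.
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k * fs / n
  f[f > fs / 2] <- f[f > fs / 2] - fs
  f
}
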