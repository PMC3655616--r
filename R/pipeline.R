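# End-to-end pipeline driver: preprocess -> spectral -> bicoherence ->
# statistics, with a run manifest for reproducibility.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain. The defaults are the
#' standard operating point: 256 Hz sampling, 1–45 Hz band-pass, 2 s epochs
#' with 75% overlap, a 0.5 Hz power grid, a 1 Hz / 2 Hz-bandwidth
#' bifrequency grid, 40 surrogates at the 95th percentile, alpha = 0.05.
#'
#' @param rate Analysis sampling rate (Hz); inputs at other rates are
#'   resampled.
#' @param band Band-pass limits `c(lo, hi)` in Hz.
#' @param epoch_len Epoch length (s).
#' @param overlap Fractional epoch overlap in `[0, 1)`.
#' @param power_grid `c(lo, hi, step)` for the Morlet power grid (Hz).
#' @param omega Morlet central angle frequency.
#' @param bifreq `c(lo, hi, step, bandwidth)` for the bicoherence grid (Hz).
#' @param surrogates Surrogate count for significance filtering; 0 disables
#'   filtering.
#' @param surrogate_prob Null quantile defining the threshold.
#' @param alpha Significance level for screens and rank-sum tests.
#' @param amp_limit,flat_limit Channel-rejection limits (microvolts
#'   peak-to-peak).
#' @param epoch_reject Epoch-rejection multiple of the median peak-to-peak.
#' @param bico_channels Channels used for bicoherence (labels); `NULL` = all.
#' @param baseline Name of the baseline session; default the first.
#' @param seed Root seed for all randomness (surrogates).
#' @return A validated list of class `eegbico_config`.
#' @export
pipeline_config <- function(rate = 256, band = c(1, 45), epoch_len = 2,
                            overlap = 0.75, power_grid = c(1, 45, 0.5),
                            omega = 6, bifreq = c(1, 45, 1, 2),
                            surrogates = 40, surrogate_prob = 0.95,
                            alpha = 0.05, amp_limit = 1000, flat_limit = 0.01,
                            epoch_reject = 6, bico_channels = NULL,
                            baseline = NULL, seed = 1) {
  assert_that(is_scalar_num(overlap) && overlap >= 0 && overlap < 1,
              "`overlap` must be in [0, 1)")
  assert_that(length(band) == 2 && band[1] > 0 && band[1] < band[2] &&
                band[2] < rate / 2, "`band` must satisfy 0 < lo < hi < rate/2")
  assert_that(length(power_grid) == 3 && length(bifreq) == 4,
              "`power_grid` needs (lo, hi, step); `bifreq` needs (lo, hi, step, bandwidth)")
  assert_that(is.numeric(surrogates) && surrogates >= 0,
              "`surrogates` must be >= 0")
  assert_that(alpha > 0 && alpha < 1, "`alpha` must be in (0, 1)")
  structure(
    list(rate = rate, band = band, epoch_len = epoch_len, overlap = overlap,
         power_grid = power_grid, omega = omega, bifreq = bifreq,
         surrogates = surrogates, surrogate_prob = surrogate_prob,
         alpha = alpha, amp_limit = amp_limit, flat_limit = flat_limit,
         epoch_reject = epoch_reject, bico_channels = bico_channels,
         baseline = baseline, seed = seed),
    class = "eegbico_config"
  )
}

#' Read / write a flat key-value configuration file
#'
#' One `key = value` pair per line; vector values are comma-separated.
#'
#' @param path File path.
#' @param config An `eegbico_config` (for writing).
#' @return `read_config()` returns an `eegbico_config`.
#' @export
read_config <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE)
  kv <- lapply(strsplit(lines, "=", fixed = TRUE), trimws)
  args <- setNames(
    lapply(kv, function(p) {
      v <- strsplit(p[2], ",")[[1]]
      nv <- suppressWarnings(as.numeric(v))
      if (anyNA(nv)) trimws(v) else nv
    }),
    vapply(kv, `[[`, "", 1)
  )
  args <- args[names(args) %in% names(formals(pipeline_config))]
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  keys <- setdiff(names(config), "bico_channels")
  if (!is.null(config$bico_channels)) keys <- names(config)
  lines <- vapply(keys, function(k) {
    if (is.null(config[[k]])) sprintf("# %s = (default)", k)
    else sprintf("%s = %s", k, paste(config[[k]], collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

preprocess_recording <- function(rec, config) {
  if (!isTRUE(all.equal(rec$fs, config$rate))) {
    rec <- resample_recording(rec, config$rate)
  }
  rec <- bandpass(rec, config$band[1], config$band[2])
  rec <- rereference_average(rec)
  rej <- reject_channels(rec, config$amp_limit, config$flat_limit)
  ep <- make_epochs(rej$recording, config$epoch_len, config$overlap)
  epr <- reject_epochs(ep, config$epoch_reject)
  list(epochs = epr$epochs, channel_report = rej$report,
       epochs_dropped = epr$dropped)
}

#' Run the full analysis pipeline
#'
#' Executes preprocess (resample, band-pass, average rereference, channel
#' and epoch rejection, epoching), Morlet band power, harmonic-wavelet
#' bicoherence with optional surrogate filtering and band-pair totals, and
#' the session statistics: per-subject change rates against the baseline
#' session, paired t screens on relative band power per channel, and
#' Wilcoxon rank-sum tests on channel-averaged band-pair coupling.
#'
#' @param recordings A named list: one entry per session, each a list of
#'   [recording()]s (one per subject, in matching subject order) or a single
#'   recording.
#' @param config An [pipeline_config()].
#' @return An `eegbico_results` list: `band_power`, `change`, `power_tests`,
#'   `coupling`, `coupling_tests`, `reports` and `manifest`. Any stage error
#'   is rethrown with the session and subject that caused it.
#' @export
run_pipeline <- function(recordings, config = pipeline_config()) {
  assert_that(is.list(recordings) && length(recordings) >= 1 &&
                !is.null(names(recordings)) && all(nzchar(names(recordings))),
              "`recordings` must be a named list of sessions")
  recordings <- lapply(recordings, function(s) {
    if (inherits(s, "eegbico_recording")) list(s) else s
  })
  baseline <- config$baseline %||% names(recordings)[1]
  assert_that(baseline %in% names(recordings), "unknown baseline session")
  sessions <- names(recordings)
  bp_all <- list(); cp_all <- list(); reports <- list()
  seeds <- with_seed(config$seed,
                     sample.int(2^30, sum(lengths(recordings))))
  si <- 0
  for (sess in sessions) {
    for (subj in seq_along(recordings[[sess]])) {
      si <- si + 1
      res <- tryCatch({
        rec <- recordings[[sess]][[subj]]
        rec$session <- sess
        pp <- preprocess_recording(rec, config)
        ep <- pp$epochs
        ps <- morlet_power(ep, grid = do.call(freq_grid, as.list(config$power_grid)),
                           omega = config$omega)
        bp <- band_power(ps) |> mutate(subject = subj, .after = "session")
        grid <- do.call(bifreq_grid, as.list(config$bifreq))
        chans <- config$bico_channels %||% ep$labels
        chans <- intersect(chans, ep$labels)
        cp <- purrr::map_dfr(chans, function(chl) {
          bic <- wavelet_bicoherence(ep, channel = chl, grid = grid)
          if (config$surrogates > 0) {
            thr <- surrogate_threshold(ep, chl, grid,
                                       n_surrogates = config$surrogates,
                                       prob = config$surrogate_prob,
                                       seed = seeds[si])
            bic <- filter_bicoherence(bic, thr)
          }
          band_pair_coupling(bic) |> mutate(channel = chl)
        }) |>
          group_by(.data$band_j, .data$band_k) |>
          summarise(coupling = mean(.data$coupling), .groups = "drop") |>
          mutate(session = sess, subject = subj, .before = 1)
        list(bp = bp, cp = cp, report = pp$channel_report,
             dropped = pp$epochs_dropped)
      }, error = function(e) {
        abort(sprintf("pipeline failed in session '%s', subject %d: %s",
                      sess, subj, conditionMessage(e)), parent = e)
      })
      bp_all[[si]] <- res$bp
      cp_all[[si]] <- res$cp
      reports[[si]] <- tibble(session = sess, subject = subj,
                              channels_rejected = nrow(res$report),
                              epochs_dropped = length(res$dropped))
    }
  }
  band_power_tb <- bind_rows(bp_all)
  coupling_tb <- bind_rows(cp_all)
  others <- setdiff(sessions, baseline)
  change_tb <- purrr::map_dfr(others, function(sess) {
    purrr::map_dfr(unique(band_power_tb$subject), function(sj) {
      aft <- filter(band_power_tb, .data$session == sess, .data$subject == sj)
      bef <- filter(band_power_tb, .data$session == baseline, .data$subject == sj)
      if (nrow(aft) == 0 || nrow(bef) == 0) return(NULL)
      change_rate(aft, bef) |> mutate(session = sess, subject = sj, .before = 1)
    })
  })
  power_tests <- purrr::map_dfr(others, function(sess) {
    dat <- filter(band_power_tb, .data$session %in% c(sess, baseline))
    if (length(unique(dat$subject)) < 2) return(NULL)
    per_channel_screen(dat, value = "relative", condition = "session",
                       unit = "subject", group_cols = c("channel", "band"),
                       test = "paired_t", alpha = config$alpha) |>
      mutate(session = sess, .before = 1)
  })
  coupling_tests <- purrr::map_dfr(others, function(sess) {
    purrr::map_dfr(
      unique(coupling_tb[, c("band_j", "band_k")] |> tidyr::unite("p", 1:2))$p,
      function(pair) {
        parts <- strsplit(pair, "_")[[1]]
        x <- filter(coupling_tb, .data$session == sess,
                    .data$band_j == parts[1], .data$band_k == parts[2])$coupling
        y <- filter(coupling_tb, .data$session == baseline,
                    .data$band_j == parts[1], .data$band_k == parts[2])$coupling
        if (!length(x) || !length(y) || anyNA(c(x, y))) return(NULL)
        wilcoxon_ranksum(x, y) |>
          mutate(session = sess, band_j = parts[1], band_k = parts[2],
                 direction = sign(median(x) - median(y)), .before = 1)
      })
  })
  if (nrow(coupling_tests)) {
    coupling_tests$significant <- !is.na(coupling_tests$p_value) &
      coupling_tests$p_value < config$alpha
  }
  manifest <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    baseline = baseline,
    sessions = sessions,
    seed = config$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("eegbico"))
  )
  structure(
    list(band_power = band_power_tb, change = change_tb,
         power_tests = power_tests, coupling = coupling_tb,
         coupling_tests = coupling_tests, reports = bind_rows(reports),
         manifest = manifest),
    class = "eegbico_results"
  )
}

#' @export
print.eegbico_results <- function(x, ...) {
  cat("<eegbico_results>\n")
  cat("  sessions:", paste(x$manifest$sessions, collapse = ", "),
      sprintf("(baseline: %s)\n", x$manifest$baseline))
  cat(sprintf("  band_power: %d rows; coupling: %d rows\n",
              nrow(x$band_power), nrow(x$coupling)))
  cat(sprintf("  power_tests: %d cells (%d significant); coupling_tests: %d pairs (%d significant)\n",
              nrow(x$power_tests), sum(x$power_tests$significant %||% 0),
              nrow(x$coupling_tests),
              if (nrow(x$coupling_tests)) sum(x$coupling_tests$significant) else 0))
  invisible(x)
}

#' Write pipeline result tables
#'
#' Writes every result table as CSV plus the run manifest as a flat
#' key-value file into `dir`.
#'
#' @param res An `eegbico_results`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("band_power", "change", "power_tests", "coupling",
               "coupling_tests", "reports")) {
    write.csv(res[[nm]], file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  mf <- res$manifest
  lines <- c(
    sprintf("config_hash = %s", mf$config_hash),
    sprintf("baseline = %s", mf$baseline),
    sprintf("sessions = %s", paste(mf$sessions, collapse = ",")),
    sprintf("seed = %s", mf$seed),
    sprintf("r_version = %s", mf$r_version),
    sprintf("package_version = %s", mf$package_version),
    vapply(names(mf$config), function(k) {
      sprintf("config.%s = %s", k, paste(mf$config[[k]] %||% "NULL", collapse = ","))
    }, "")
  )
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Boxplots of band-power change rates
#'
#' @param change The `change` table from [run_pipeline()].
#' @param measure `"change_relative"` or `"change_absolute"`.
#' @return A ggplot.
#' @export
plot_band_change <- function(change, measure = "change_relative") {
  ggplot2::ggplot(change,
                  ggplot2::aes(.data$band, .data[[measure]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~session) +
    ggplot2::labs(x = NULL, y = "Change rate (%)") +
    ggplot2::theme_minimal()
}

#' Boxplots of band-pair coupling by session
#'
#' @param coupling The `coupling` table from [run_pipeline()].
#' @return A ggplot.
#' @export
plot_coupling <- function(coupling) {
  dat <- mutate(coupling, pair = paste(.data$band_j, .data$band_k, sep = "-"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$pair, .data$coupling,
                                    fill = .data$session)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "Band pair", y = "Total coupling b") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
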