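#' Construct a multichannel EEG recording
#'
#' The basic signal container: a channels-by-samples numeric matrix of
#' amplitudes (conventionally microvolts) together with its sampling rate,
#' channel labels, an optional planar montage and a session tag (for example
#' `"before_incision"`, `"after_incision"`, `"after_treatment"`).
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in samples per second.
#' @param labels Character vector of unique channel names; defaults to the
#'   rownames of `data` or `"ch01"`, `"ch02"`, ...
#' @param montage Optional montage tibble as returned by [rat_montage()] or
#'   [read_montage()]; must cover every label used for topography.
#' @param session Free-text session tag carried through the pipeline.
#'
#' @return An object of class `eegbico_recording`.
#' @seealso [tidy.eegbico_recording()] for a long-tibble view,
#'   [make_epochs()], [bandpass()].
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(512), 2, 256), fs = 256)
#' rec
recording <- function(data, fs, labels = NULL, montage = NULL, session = NA_character_) {
  assert_that(is.matrix(data) && is.numeric(data), "`data` must be a numeric matrix (channels x samples)")
  assert_that(is_scalar_num(fs) && fs > 0, "`fs` must be a positive scalar")
  if (is.null(labels)) {
    labels <- rownames(data) %||% sprintf("ch%02d", seq_len(nrow(data)))
  }
  assert_that(length(labels) == nrow(data), "`labels` length must equal the number of channels")
  assert_that(!anyDuplicated(labels), "channel labels must be unique")
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels, montage = montage,
         session = session),
    class = "eegbico_recording"
  )
}

#' @export
print.eegbico_recording <- function(x, ...) {
  cat(sprintf("<eegbico_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.na(x$session)) cat("  session:", x$session, "\n")
  cat("  channels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.eegbico_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)

#' Tidy a recording into a long tibble
#'
#' @param x An `eegbico_recording`.
#' @param ... Unused.
#' @return A tibble with columns `channel`, `time` (s) and `amplitude`.
#' @method tidy eegbico_recording
#' @export
tidy.eegbico_recording <- function(x, ...) {
  tibble(
    channel = rep(x$labels, each = ncol(x$data)),
    time = rep(seq_len(ncol(x$data)) - 1, times = nrow(x$data)) / x$fs,
    amplitude = as.vector(t(x$data))
  )
}

#' @method glance eegbico_recording
#' @export
glance.eegbico_recording <- function(x, ...) {
  tibble(n_channels = nrow(x$data), n_samples = ncol(x$data), fs = x$fs,
         duration_s = ncol(x$data) / x$fs, session = x$session)
}

#' The 14-electrode epidural rat montage
#'
#' Planar coordinates (anterior/posterior and lateral, mm relative to bregma)
#' of the 12 scalp screw electrodes used for topographic maps, plus the
#' reference and ground electrodes (flagged `scalp = FALSE`, no map
#' coordinates: they sit caudal to lambda, off the mapped grid). The printed
#' source coordinates carry an ambiguity for the centrofrontal group (an
#' anterior "+/-1.5 mm" for FL2/FR2/PL1/PR1); the packaged file resolves it by
#' placing the frontal pair anterior (+1.5) and the parietal pair posterior
#' (-1.5), and keeps the lateral signs left-negative/right-positive.
#'
#' @return A tibble with columns `label`, `anterior_mm`, `lateral_mm`, `scalp`.
#' @export
#' @examples
#' rat_montage()
rat_montage <- function() {
  path <- system.file("extdata", "rat_montage_14.csv", package = "eegbico")
  read_montage(path)
}

#' Read a montage file
#'
#' A montage is a delimited table with columns `label`, `anterior_mm`,
#' `lateral_mm` and optionally `scalp` (logical; defaults to `TRUE` where
#' coordinates are present).
#'
#' @param path Path to a CSV montage file.
#' @return A montage tibble.
#' @export
read_montage <- function(path) {
  m <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  assert_that(all(c("label", "anterior_mm", "lateral_mm") %in% names(m)),
              "montage file needs columns label, anterior_mm, lateral_mm")
  if (!"scalp" %in% names(m)) m$scalp <- !is.na(m$anterior_mm)
  assert_that(!anyDuplicated(m$label), "montage labels must be unique")
  m
}
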