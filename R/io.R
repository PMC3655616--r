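# Recording and sequence I/O: delimited matrices, EDF, up-down tables.

#' Write a recording to disk
#'
#' Two interchange formats are supported: `"csv"`, a delimited matrix with one
#' row per channel (first column `label`, then one column per sample, preceded
#' by a single comment line holding the sampling rate and session tag), and
#' `"edf"`, the 16-bit European Data Format common in EEG.
#'
#' @param rec An [recording()].
#' @param path Output file path.
#' @param format `"csv"` or `"edf"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = NULL) {
  format <- format %||% if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  switch(match.arg(format, c("csv", "edf")),
    csv = {
      con <- file(path, "w")
      on.exit(close(con))
      cat(sprintf("#eegbico fs=%g session=%s\n", rec$fs,
                  ifelse(is.na(rec$session), "NA", rec$session)), file = con)
      df <- data.frame(label = rec$labels, rec$data, check.names = FALSE)
      write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE,
                  quote = FALSE)
    },
    edf = write_edf(rec, path)
  )
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path Path to a file written by [write_recording()] (CSV with the
#'   `#eegbico` header line) or any 16-bit EDF file.
#' @param format `"csv"` or `"edf"`; guessed from the extension by default.
#' @return An [recording()].
#' @export
read_recording <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  switch(match.arg(format, c("csv", "edf")),
    csv = {
      first <- readLines(path, n = 1)
      assert_that(grepl("^#eegbico", first), "missing #eegbico header line in delimited recording")
      fs <- as.numeric(sub(".*fs=([0-9.eE+-]+).*", "\\1", first))
      session <- sub(".*session=(\\S+).*", "\\1", first)
      if (identical(session, "NA")) session <- NA_character_
      df <- read.csv(path, header = FALSE, skip = 1, stringsAsFactors = FALSE)
      labels <- as.character(df[[1]])
      data <- as.matrix(df[, -1, drop = FALSE])
      dimnames(data) <- NULL
      recording(data, fs = fs, labels = labels, session = session)
    },
    edf = read_edf(path)
  )
}

# --- minimal EDF (16-bit) writer/reader -------------------------------------
# Fixed-layout ASCII header (256 bytes + 256 per signal) followed by data
# records of little-endian 16-bit integers. One physical scaling per channel.

edf_pad <- function(x, width) {
  x <- substr(format(x, width = width), 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path, record_duration = 1) {
  fs <- rec$fs
  assert_that(abs(fs * record_duration - round(fs * record_duration)) < 1e-9,
              "record duration must give an integer number of samples")
  spr <- as.integer(round(fs * record_duration))       # samples per record
  ns <- nrow(rec$data)
  n_full <- ncol(rec$data) %/% spr                     # trailing partial dropped
  assert_that(n_full >= 1, "recording shorter than one EDF data record")
  pmin <- apply(rec$data, 1, min); pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("eegbico", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(as.character(256 * (1 + ns)), 8), edf_pad("", 44),
    edf_pad(as.character(n_full), 8),
    edf_pad(format(record_duration), 8), edf_pad(as.character(ns), 4),
    paste(edf_pad(rec$labels, 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(edf_pad(formatC(pmin, digits = 5, format = "g"), 8), collapse = ""),
    paste(edf_pad(formatC(pmax, digits = 5, format = "g"), 8), collapse = ""),
    paste(rep(edf_pad(as.character(dmin), 8), ns), collapse = ""),
    paste(rep(edf_pad(as.character(dmax), 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(as.character(spr), 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_full)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((rec$data[ch, idx] - pmin[ch]) * scale[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)                         # transducer
  for (i in seq_len(ns)) rd(8)                          # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)                         # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  assert_that(length(unique(spr)) == 1, "channels with differing rates are not supported")
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little",
                     signed = TRUE)
      phys <- (dig - dmin[ch]) * (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch]) + pmin[ch]
      data[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  recording(data, fs = fs, labels = labels)
}

#' Write / read an up-down trial sequence
#'
#' Sequences travel as a two-column delimited table (`force_g`,
#' `response` with 1 = positive withdrawal, 0 = negative).
#'
#' @param seq An `eegbico_updown` sequence (see [simulate_updown()]).
#' @param path File path.
#' @return `write_updown()` returns `path` invisibly; `read_updown()` returns
#'   an `eegbico_updown` object rebuilt from the table.
#' @export
write_updown <- function(seq, path) {
  write.csv(seq$trials[, c("force_g", "response")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_updown
#' @export
read_updown <- function(path) {
  df <- read.csv(path)
  assert_that(all(c("force_g", "response") %in% names(df)),
              "up-down table needs columns force_g and response")
  new_updown(df$force_g, as.integer(df$response))
}
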