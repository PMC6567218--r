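#' Multichannel EEG recording
#'
#' Container for a channels-by-samples matrix in microvolts with its sampling
#' rate and channel labels.  At least two channels are required, all values
#' must be finite, and labels must be unique.
#'
#' @param data Numeric matrix, one row per channel, one column per sample.
#' @param fs Sampling rate in Hz (> 0).
#' @param labels Character vector of channel names; defaults to
#'   `"ch1"..."chN"`.
#' @return An object of class `uar_recording` with fields `data`, `fs`,
#'   `labels`.
#' @examples
#' rec <- recording(matrix(rnorm(512), nrow = 2), fs = 256)
#' n_samples(rec)
#' @export
recording <- function(data, fs, labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  rec <- structure(list(data = data, fs = as.numeric(fs), labels = labels),
                   class = "uar_recording")
  validate_recording(rec)
}

validate_recording <- function(rec) {
  if (!is.matrix(rec$data) || !is.numeric(rec$data))
    stop("recording data must be a numeric matrix (channels x samples)")
  if (nrow(rec$data) < 2)
    stop("recording needs at least 2 channels, got ", nrow(rec$data))
  if (!all(is.finite(rec$data)))
    stop("recording contains non-finite values")
  if (length(rec$fs) != 1 || !is.finite(rec$fs) || rec$fs <= 0)
    stop("sampling rate fs must be a single positive number")
  if (length(rec$labels) != nrow(rec$data))
    stop("label count (", length(rec$labels), ") does not match channel count (",
         nrow(rec$data), ")")
  if (anyDuplicated(rec$labels))
    stop("channel labels must be unique")
  rec
}

#' @rdname recording
#' @param rec A `uar_recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @export
print.uar_recording <- function(x, ...) {
  cat(sprintf("uar_recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              n_channels(x), n_samples(x), x$fs, n_samples(x) / x$fs))
  cat("  labels:", paste(head(x$labels, 8), collapse = ", "),
      if (n_channels(x) > 8) "..." else "", "\n")
  invisible(x)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         edf = "edf", bdf = "bdf", csv = "csv", bin = "bin",
         stop("cannot guess recording format from extension '.", ext, "'"))
}

#' Read a multichannel recording from disk
#'
#' Supported formats: `edf` / `bdf` (16-/24-bit European Data Format, sampling
#' rate and labels honoured from the header), `csv` (one row per channel, no
#' header; `fs` must be supplied), and `bin` (raw little-endian float64 with a
#' JSON sidecar `<path>.json` holding `fs`, dims and labels).
#'
#' @param path Input file.
#' @param format One of `"auto"`, `"edf"`, `"bdf"`, `"csv"`, `"bin"`.
#' @param fs Sampling rate in Hz; required for `csv`, ignored for
#'   self-describing formats.
#' @param labels Optional channel labels for `csv`.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = "auto", fs = NULL, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (identical(format, "auto")) format <- guess_format(path)
  format <- match.arg(format, c("edf", "bdf", "csv", "bin"))
  switch(format,
         csv = read_recording_csv(path, fs, labels),
         bin = read_recording_bin(path),
         edf = read_edf(path, bits = 16),
         bdf = read_edf(path, bits = 24))
}

#' Write a multichannel recording to disk
#'
#' Inverse of [read_recording()].  CSV and bin round-trips are lossless;
#' EDF/BDF round-trips are exact up to the 16-/24-bit quantisation step
#' implied by the per-channel physical range.
#'
#' @param rec A [recording()].
#' @param path Output file.
#' @param format One of `"auto"`, `"edf"`, `"bdf"`, `"csv"`, `"bin"`.
#' @export
write_recording <- function(rec, path, format = "auto") {
  validate_recording(rec)
  if (identical(format, "auto")) format <- guess_format(path)
  format <- match.arg(format, c("edf", "bdf", "csv", "bin"))
  switch(format,
         csv = write_recording_csv(rec, path),
         bin = write_recording_bin(rec, path),
         edf = write_edf(rec, path, bits = 16),
         bdf = write_edf(rec, path, bits = 24))
  invisible(path)
}

read_recording_csv <- function(path, fs, labels) {
  if (is.null(fs))
    stop("fs must be supplied when reading a CSV recording (the format carries no header)")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty CSV recording: ", path)
  rows <- lapply(strsplit(lines, ","), function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop("non-numeric value in CSV recording: ", path)
    v
  })
  if (length(unique(lengths(rows))) != 1)
    stop("CSV rows (channels) have mismatched lengths")
  recording(do.call(rbind, rows), fs = fs, labels = labels)
}

write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_channels(rec)))
    writeLines(paste(sprintf("%.17g", rec$data[i, ]), collapse = ","), con)
}

read_recording_bin <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing sidecar metadata: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  x <- readBin(path, "double", n = n, size = 8, endian = "little")
  if (length(x) != n) stop("binary recording shorter than sidecar dims: ", path)
  recording(matrix(x, nrow = meta$n_channels, byrow = TRUE),
            fs = meta$fs, labels = meta$labels)
}

write_recording_bin <- function(rec, path) {
  writeBin(as.vector(t(rec$data)), path, size = 8, endian = "little")
  jsonlite::write_json(
    list(n_channels = n_channels(rec), n_samples = n_samples(rec),
         fs = rec$fs, labels = rec$labels, dtype = "float64le"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
}

# ---- EDF / BDF ---------------------------------------------------------
# Minimal single-data-record EDF (16-bit) / BDF (24-bit) writer and reader.
# One data record holds the whole signal; physical dimension is microvolts.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

write_edf <- function(rec, path, bits = 16) {
  ns <- n_channels(rec); np <- n_samples(rec)
  dig_max <- if (bits == 16) 32767 else 8388607
  dig_min <- -dig_max - 1
  pmin <- apply(rec$data, 1, min); pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  # pad so the 6-significant-digit header values stay outside the data range
  # (otherwise extremes would clip); widens the quantisation step by < 0.1%
  slack <- 1e-4 * (abs(pmin) + abs(pmax)) + 1e-9
  pmin <- pmin - slack; pmax <- pmax + slack

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    if (bits == 16) pad_field("0", 8) else NULL,
    pad_field("synthetic recording", 80),
    pad_field("uareeg", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1) + if (bits == 24) 0 else 0, 8),
    pad_field(if (bits == 24) "24BIT" else "", 44),
    pad_field("1", 8),
    pad_field(sprintf("%.6g", np / rec$fs), 8),
    pad_field(ns, 4))
  if (bits == 24) {
    writeBin(as.raw(255), con)
    writeChar(pad_field("BIOSEMI", 7), con, eos = NULL)
  }
  writeChar(paste(hdr, collapse = ""), con, eos = NULL)
  per <- function(vals, width)
    writeChar(paste(vapply(vals, pad_field, "", width), collapse = ""), con, eos = NULL)
  per(rec$labels, 16)
  per(rep("", ns), 80)                       # transducer
  per(rep("uV", ns), 8)                      # physical dimension
  per(sprintf("%.6g", pmin), 8)
  per(sprintf("%.6g", pmax), 8)
  per(rep(dig_min, ns), 8)
  per(rep(dig_max, ns), 8)
  per(rep("", ns), 80)                       # prefiltering
  per(rep(np, ns), 8)                        # samples per record
  per(rep("", ns), 32)

  # header fields were written with %.6g; quantise against the parsed values
  pmin_h <- as.numeric(sprintf("%.6g", pmin))
  pmax_h <- as.numeric(sprintf("%.6g", pmax))
  for (i in seq_len(ns)) {
    scale <- (pmax_h[i] - pmin_h[i]) / (dig_max - dig_min)
    dig <- round((rec$data[i, ] - pmin_h[i]) / scale) + dig_min
    dig <- pmin(pmax(dig, dig_min), dig_max)
    if (bits == 16) {
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    } else {
      v <- as.integer(dig)
      bytes <- rbind(bitwAnd(v, 255L),
                     bitwAnd(bitwShiftR(v, 8L), 255L),
                     bitwAnd(bitwShiftR(v + ifelse(v < 0, 16777216L, 0L), 16L), 255L))
      writeBin(as.raw(bytes), con)
    }
  }
}

read_edf <- function(path, bits = 16) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not a valid EDF/BDF file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "raw", 1)
  magic <- readChar(con, 7, useBytes = TRUE)
  if (bits == 24 && !(first == as.raw(255) && magic == "BIOSEMI"))
    stop("not a BDF file: ", path)
  if (bits == 16 && !(first == as.raw(48)))  # '0'
    stop("not an EDF file: ", path)
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                      # header length
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("corrupt EDF/BDF header: ", path)
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80)
  dims <- rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  nspr <- as.integer(rdv(8))
  rdv(32)
  if (any(!dims %in% c("uV", "")))
    warning("EDF physical dimension is not microvolts for all channels: ",
            paste(unique(dims), collapse = ", "))
  data <- matrix(0, nrow = ns, ncol = sum(rep(nspr[1], n_rec)))
  col0 <- 0L
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (bits == 16) {
        dig <- readBin(con, "integer", n = nspr[i], size = 2,
                       endian = "little", signed = TRUE)
      } else {
        raw3 <- readBin(con, "raw", n = 3L * nspr[i])
        m <- matrix(as.integer(raw3), nrow = 3)
        dig <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        dig <- ifelse(dig >= 8388608, dig - 16777216, dig)
      }
      scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
      data[i, col0 + seq_len(nspr[i])] <- pmin[i] + scale * (dig - dmin[i])
    }
    col0 <- col0 + nspr[1]
  }
  fs <- nspr[1] / rec_dur
  recording(data, fs = fs, labels = labels)
}

#' Notch (band-stop) filter for mains interference
#'
#' Removes a narrow band around the mains frequency with a zero-phase
#' second-order IIR notch (zeros on the unit circle at the mains frequency,
#' poles at radius 0.985), applied forward-backward so the passband is left
#' essentially untouched outside a ±2 Hz neighbourhood of the notch.
#'
#' @param rec A [recording()].
#' @param mains_hz Mains frequency in Hz (must be below Nyquist).
#' @return A filtered [recording()].
#' @export
notch_filter <- function(rec, mains_hz) {
  validate_recording(rec)
  if (mains_hz <= 0 || mains_hz >= rec$fs / 2)
    stop("mains_hz must lie in (0, fs/2), got ", mains_hz)
  w0 <- 2 * pi * mains_hz / rec$fs
  r <- 0.985
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  # normalise passband (DC) gain to 1
  k <- sum(a) / sum(b)
  b <- b * k
  out <- rec
  for (i in seq_len(n_channels(rec)))
    out$data[i, ] <- signal::filtfilt(signal::Arma(b = b, a = a), rec$data[i, ])
  out
}
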