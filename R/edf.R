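# Minimal EDF (European Data Format) I/O.
#
# EDF stores a fixed-width ASCII header followed by 16-bit little-endian
# data records; physical values are recovered by the per-signal linear
# digital->physical calibration. Only equal-rate signals are supported:
# EEG-only files such as CHB-MIT. No R EDF reader is available in this
# stack, so the format is parsed directly.

edf_field <- function(con, n) {
  raw <- readChar(con, n, useBytes = TRUE)
  if (nchar(raw, type = "bytes") < n)
    stop("unreadable EDF file: truncated header", call. = FALSE)
  trimws(raw)
}

#' Read an EDF recording
#'
#' Reads all signals of an EDF file at their native rate, converted to
#' physical units (µV for EEG) via the header calibration.
#'
#' @param path path to an EDF file.
#' @return an [eeg_recording()].
#' @details All signals must share one sampling rate; files mixing rates
#'   (e.g. an auxiliary annotation signal) are rejected with an error that
#'   names the offending channels.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  edf_field(con, 8)                      # version
  edf_field(con, 80); edf_field(con, 80) # patient / recording id
  edf_field(con, 8); edf_field(con, 8)   # start date / time
  header_bytes <- as.integer(edf_field(con, 8))
  edf_field(con, 44)
  n_records <- as.integer(edf_field(con, 8))
  record_dur <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1L || is.na(n_records) || is.na(record_dur))
    stop("unreadable EDF file: corrupt header", call. = FALSE)

  sig_field <- function(n) vapply(seq_len(ns), function(i) edf_field(con, n), "")
  labels <- sig_field(16)
  sig_field(80)                          # transducer
  sig_field(8)                           # physical dimension
  pmin <- as.numeric(sig_field(8)); pmax <- as.numeric(sig_field(8))
  dmin <- as.numeric(sig_field(8)); dmax <- as.numeric(sig_field(8))
  sig_field(80)                          # prefiltering
  spr <- as.integer(sig_field(8))        # samples per data record
  sig_field(32)
  if (isTRUE(header_bytes != 256L + 256L * ns))
    stop("unreadable EDF file: header size mismatch", call. = FALSE)

  if (length(unique(spr)) != 1L) {
    rates <- spr / record_dur
    bad <- labels[rates != stats::median(rates)]
    stop("EDF signals with differing sampling rates: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fs <- spr[1] / record_dur

  need <- as.numeric(n_records) * ns * spr[1]
  vals <- readBin(con, "integer", n = need, size = 2L,
                  signed = TRUE, endian = "little")
  if (length(vals) < need)
    stop("unreadable EDF file: truncated data records", call. = FALSE)

  # records are channel-blocked: record-major, then channel, then sample
  arr <- array(vals, dim = c(spr[1], ns, n_records))
  data <- matrix(0, nrow = ns, ncol = spr[1] * n_records)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (ch in seq_len(ns)) {
    dig <- as.vector(arr[, ch, ])
    data[ch, ] <- (dig - dmin[ch]) * scale[ch] + pmin[ch]
  }
  if (anyDuplicated(labels))
    labels <- make.unique(labels)
  eeg_recording(data, fs = fs, channel_labels = labels)
}

#' Write an EDF recording
#'
#' Writes an [eeg_recording()] as a single-record-per-second EDF file with
#' 16-bit quantisation over the observed amplitude range. Intended for
#' fixtures and round-trip tests, not clinical archiving.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  fs <- rec$fs
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate", call. = FALSE)
  spr <- as.integer(fs)
  n_records <- floor(ncol(rec$data) / spr)
  if (n_records < 1L) stop("recording shorter than one 1-s data record", call. = FALSE)
  used <- seq_len(n_records * spr)

  pmin <- apply(rec$data[, used, drop = FALSE], 1, min)
  pmax <- apply(rec$data[, used, drop = FALSE], 1, max)
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767

  pad <- function(x, n) {
    s <- substr(format(x, trim = TRUE, scientific = FALSE), 1, n)
    formatC(s, width = n, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("synthetic", 80), pad("vmdseiz fixture", 80),
                pad("01.01.00", 8), pad("00.00.00", 8),
                pad(256L + 256L * ns, 8), pad("", 44),
                pad(n_records, 8), pad(1, 8), pad(ns, 4))
  sig <- function(vals, n) paste(vapply(vals, pad, "", n = n), collapse = "")
  hdr <- paste0(hdr,
                sig(rec$channel_labels, 16), sig(rep("", ns), 80),
                sig(rep("uV", ns), 8),
                sig(formatC(pmin, digits = 6, format = "g"), 8),
                sig(formatC(pmax, digits = 6, format = "g"), 8),
                sig(rep(dmin, ns), 8), sig(rep(dmax, ns), 8),
                sig(rep("", ns), 80), sig(rep(spr, ns), 8), sig(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  # re-read the rounded header calibration so the round trip is exact
  pmin_h <- as.numeric(formatC(pmin, digits = 6, format = "g"))
  pmax_h <- as.numeric(formatC(pmax, digits = 6, format = "g"))
  for (r in seq_len(n_records)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((rec$data[ch, idx] - pmin_h[ch]) /
                     (pmax_h[ch] - pmin_h[ch]) * (dmax - dmin) + dmin)
      writeBin(as.integer(clamp(dig, dmin, dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}
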