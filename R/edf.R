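# Minimal EDF (European Data Format) I/O: 16-bit little-endian samples,
# continuous recording, one sampling rate shared by all channels. Covers the
# subset of the format this package writes; not a general-purpose EDF reader.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write an EEG record as EDF
#'
#' Writes a single continuous data record with 16-bit samples scaled per
#' channel between the physical minimum and maximum. Values round-trip within
#' one 16-bit quantization step of the channel's physical range.
#'
#' @param record an `eeg_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  ns <- nrow(record$samples)
  n <- ncol(record$samples)
  dig_min <- -32767L; dig_max <- 32767L
  phys <- t(apply(record$samples, 1, range))
  # guard degenerate flat channels
  flat <- phys[, 1] == phys[, 2]
  phys[flat, 1] <- phys[flat, 1] - 1
  phys[flat, 2] <- phys[flat, 2] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X", 80), edf_pad("X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(1, 8), edf_pad(format(n / record$fs, digits = 7), 8),
    edf_pad(ns, 4),
    paste(edf_pad(record$channel_labels, 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(edf_pad(formatC(phys[, 1], format = "g", digits = 6), 8), collapse = ""),
    paste(edf_pad(formatC(phys[, 2], format = "g", digits = 6), 8), collapse = ""),
    paste(rep(edf_pad(dig_min, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(n, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  # re-read the ASCII physical limits so scaling matches what a reader sees
  pmin <- as.numeric(formatC(phys[, 1], format = "g", digits = 6))
  pmax <- as.numeric(formatC(phys[, 2], format = "g", digits = 6))
  for (ch in seq_len(ns)) {
    g <- (dig_max - dig_min) / (pmax[ch] - pmin[ch])
    dig <- as.integer(round((record$samples[ch, ] - pmin[ch]) * g + dig_min))
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any continuous 16-bit EDF
#' whose channels share one sampling rate)
#'
#' @param path EDF file path.
#' @return an `eeg_record`.
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not a valid EDF file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("not a valid EDF file: ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)              # transducer
  for (i in seq_len(ns)) rd(8)               # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)              # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  seek(con, hdr_bytes)
  out <- vector("list", ns)
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      if (length(dig) != spr[ch]) stop("EDF data truncated: ", path)
      phys <- pmin[ch] + (dig - dmin[ch]) * (pmax[ch] - pmin[ch]) /
        (dmax[ch] - dmin[ch])
      out[[ch]] <- c(out[[ch]], phys)
    }
  }
  if (length(unique(spr)) != 1)
    stop("EDF channels with differing sampling rates are not supported")
  fs <- spr[1] / rec_dur
  eeg_record(do.call(rbind, out), fs, labels)
}
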