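#' Construct an EEG record
#'
#' An `eeg_record` holds multichannel EEG as a channels-by-time matrix of
#' microvolt samples with a single sampling frequency and unique channel
#' labels (10-20 convention, e.g. `"F4"` for referential or `"F4-C4"` for
#' bipolar channels).
#'
#' @param samples numeric matrix, channels x time, in microvolts. A vector is
#'   treated as a single channel.
#' @param fs sampling frequency in Hz (> 0).
#' @param channel_labels character vector of unique labels, one per row of
#'   `samples`.
#' @return an object of class `eeg_record` with fields `samples`, `fs`,
#'   `channel_labels`.
#' @export
eeg_record <- function(samples, fs, channel_labels = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix (channels x time)")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a single positive number")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples))
    stop("`channel_labels` must have one entry per channel row")
  if (anyDuplicated(channel_labels))
    stop("`channel_labels` must be unique")
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs, channel_labels = channel_labels),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channel(s), %.1f s @ %g Hz\n",
              nrow(x$samples), ncol(x$samples) / x$fs, x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a record or annotation in seconds
#' @param x an `eeg_record` or `annotation`.
#' @return duration in seconds.
#' @export
duration_s <- function(x) {
  if (inherits(x, "eeg_record")) return(ncol(x$samples) / x$fs)
  if (inherits(x, "annotation")) return(length(x$labels) / x$fs)
  stop("unsupported type")
}

#' Default bipolar montage pairs
#'
#' The eight anode-cathode electrode pairs used for preterm burst analysis:
#' F4-C4, C4-O2, F3-C3, C3-O1, T4-C4, C4-Cz, Cz-C3, C3-T3.
#'
#' @return a list of length-2 character vectors (anode, cathode).
#' @export
default_montage_pairs <- function() {
  list(c("F4", "C4"), c("C4", "O2"), c("F3", "C3"), c("C3", "O1"),
       c("T4", "C4"), c("C4", "Cz"), c("Cz", "C3"), c("C3", "T3"))
}

#' Derive a bipolar montage
#'
#' Forms bipolar channels as sample-wise differences anode - cathode from a
#' referential record. The sampling frequency is preserved and output channels
#' are named `"anode-cathode"`.
#'
#' @param record an `eeg_record` with referential channels.
#' @param pairs list of (anode, cathode) label pairs; defaults to
#'   [default_montage_pairs()].
#' @return an `eeg_record` of bipolar channels.
#' @export
derive_bipolar_montage <- function(record, pairs = default_montage_pairs()) {
  stopifnot(inherits(record, "eeg_record"))
  labs <- record$channel_labels
  needed <- unique(unlist(pairs))
  missing <- setdiff(needed, labs)
  if (length(missing))
    stop("electrode(s) not present in record: ", paste(missing, collapse = ", "))
  out <- t(vapply(pairs, function(p) {
    record$samples[p[1], ] - record$samples[p[2], ]
  }, numeric(ncol(record$samples))))
  eeg_record(out, record$fs,
             vapply(pairs, function(p) paste(p, collapse = "-"), ""))
}

#' Read an EEG record from file
#'
#' Supports the package CSV dialect (one column per channel, header row with
#' channel labels, first line a `# fs: <Hz>` comment) and EDF (European Data
#' Format, 16-bit).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @return an `eeg_record`.
#' @export
load_eeg <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") return(read_edf(path))
  read_eeg_csv(path)
}

read_eeg_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) stop("empty or malformed EEG CSV: ", path)
  m <- regmatches(first, regexec("^#\\s*fs\\s*[:=]\\s*([0-9.]+)", first))[[1]]
  if (length(m) < 2) stop("EEG CSV missing '# fs: <Hz>' header line: ", path)
  fs <- as.numeric(m[2])
  dat <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!nrow(dat)) stop("EEG CSV has no samples: ", path)
  eeg_record(t(as.matrix(dat)), fs, colnames(dat))
}

#' Write an EEG record to the package CSV dialect
#'
#' @param record an `eeg_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %g", record$fs), con)
  utils::write.csv(as.data.frame(t(record$samples), check.names = FALSE),
                   con, row.names = FALSE)
  invisible(path)
}
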