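#' Per-sample burst / inter-burst annotation
#'
#' Labels are stored as an integer vector with `1` = burst, `0` = inter-burst
#' and `NA` = undefined (no label, or no consensus). Character input using the
#' labels `"burst"`, `"inter_burst"`, `"undefined"` is converted.
#'
#' @param labels integer (1/0/NA), logical, or character vector of labels.
#' @param fs label sampling rate in Hz.
#' @return an object of class `annotation` with fields `labels` and `fs`.
#' @export
annotation <- function(labels, fs) {
  if (is.character(labels)) {
    lab <- rep(NA_integer_, length(labels))
    lab[labels == "burst"] <- 1L
    lab[labels == "inter_burst"] <- 0L
    bad <- !labels %in% c("burst", "inter_burst", "undefined")
    if (any(bad)) stop("unknown label(s): ", paste(unique(labels[bad]), collapse = ", "))
    labels <- lab
  }
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!is.numeric(labels)) stop("`labels` must be integer, logical or character")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L, NA_integer_)))
    stop("`labels` must be 1 (burst), 0 (inter-burst) or NA (undefined)")
  if (length(labels) == 0) stop("`labels` must be non-empty")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a single positive number")
  structure(list(labels = labels, fs = fs), class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<annotation> %.1f s @ %g Hz: %.1f%% burst, %.1f%% inter-burst, %.1f%% undefined\n",
              n / x$fs, x$fs,
              100 * sum(x$labels == 1L, na.rm = TRUE) / n,
              100 * sum(x$labels == 0L, na.rm = TRUE) / n,
              100 * sum(is.na(x$labels)) / n))
  invisible(x)
}

label_names <- function(labels) {
  out <- rep("undefined", length(labels))
  out[!is.na(labels) & labels == 1L] <- "burst"
  out[!is.na(labels) & labels == 0L] <- "inter_burst"
  out
}

#' Consensus of two reviewers' annotations
#'
#' Sample-wise: keeps the label where both reviewers agree and neither is
#' undefined; all other samples become undefined. Symmetric in its arguments.
#'
#' @param a1,a2 `annotation` objects with equal `fs` and length.
#' @return an `annotation`.
#' @export
consensus_annotation <- function(a1, a2) {
  stopifnot(inherits(a1, "annotation"), inherits(a2, "annotation"))
  if (a1$fs != a2$fs) stop("annotations have different sampling rates")
  if (length(a1$labels) != length(a2$labels))
    stop("annotations have different lengths")
  agree <- !is.na(a1$labels) & !is.na(a2$labels) & a1$labels == a2$labels
  out <- rep(NA_integer_, length(a1$labels))
  out[agree] <- a1$labels[agree]
  annotation(out, a1$fs)
}

#' Run-length segments of an annotation
#'
#' Internal workhorse: contiguous runs of identical labels (undefined included)
#' with half-open sample index ranges and second-unit times.
#' @noRd
annotation_runs <- function(a) {
  r <- rle(ifelse(is.na(a$labels), -1L, a$labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts, end = ends,               # half-open, 0-based samples
             start_s = starts / a$fs, end_s = ends / a$fs,
             label = ifelse(r$values == -1L, NA_integer_, r$values))
}

#' Convert an annotation to a labelled interval list
#'
#' Intervals are half-open `[start_s, end_s)` in seconds from a 0-based time
#' origin; undefined stretches produce no interval.
#'
#' @param a an `annotation`.
#' @return a data.frame with columns `start_s`, `end_s`, `label`
#'   (`"burst"`/`"inter_burst"`), sorted, non-overlapping.
#' @export
annotation_to_intervals <- function(a) {
  stopifnot(inherits(a, "annotation"))
  runs <- annotation_runs(a)
  runs <- runs[!is.na(runs$label), , drop = FALSE]
  data.frame(start_s = runs$start_s, end_s = runs$end_s,
             label = label_names(runs$label), stringsAsFactors = FALSE)
}

#' Convert a labelled interval list to a per-sample annotation
#'
#' @param intervals data.frame with `start_s`, `end_s`, `label`; half-open
#'   `[start_s, end_s)` seconds, non-overlapping.
#' @param fs output label rate in Hz.
#' @param duration_s total annotation duration in seconds; samples not covered
#'   by any interval are undefined.
#' @return an `annotation`.
#' @export
intervals_to_annotation <- function(intervals, fs, duration_s) {
  n <- round(duration_s * fs)
  if (n < 1) stop("duration too short for one sample")
  labels <- rep(NA_integer_, n)
  if (nrow(intervals)) {
    iv <- intervals[order(intervals$start_s), , drop = FALSE]
    if (any(iv$start_s >= iv$end_s)) stop("intervals must satisfy start < end")
    if (any(iv$end_s[-nrow(iv)] > iv$start_s[-1] + 1e-9))
      stop("intervals overlap")
    code <- ifelse(iv$label == "burst", 1L,
                   ifelse(iv$label == "inter_burst", 0L, NA_integer_))
    for (i in seq_len(nrow(iv))) {
      from <- round(iv$start_s[i] * fs) + 1L
      to <- round(iv$end_s[i] * fs)
      if (to >= from) labels[from:min(to, n)] <- code[i]
    }
  }
  annotation(labels, fs)
}

#' Read / write interval CSV (columns start_s, end_s, label)
#' @param path CSV path.
#' @return a data.frame of intervals.
#' @export
read_intervals_csv <- function(path) {
  iv <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(iv)))
    stop("interval CSV must have columns start_s, end_s, label: ", path)
  iv[need]
}

#' @rdname read_intervals_csv
#' @param intervals data.frame of intervals.
#' @export
write_intervals_csv <- function(intervals, path) {
  utils::write.csv(intervals, path, row.names = FALSE)
  invisible(path)
}

#' Resample an annotation to a new label rate
#'
#' Nearest-neighbour label lookup (labels are categorical; interpolation is
#' meaningless). Sample n of the output takes the label of the input sample
#' whose centre time is nearest.
#'
#' @param a an `annotation`.
#' @param fs_out target rate in Hz.
#' @param n_out optional output length in samples (defaults to the rounded
#'   duration at `fs_out`).
#' @return an `annotation` at `fs_out`.
#' @export
resample_annotation <- function(a, fs_out, n_out = NULL) {
  stopifnot(inherits(a, "annotation"))
  if (is.null(n_out)) n_out <- round(length(a$labels) / a$fs * fs_out)
  t_out <- (seq_len(n_out) - 0.5) / fs_out
  idx <- pmin(pmax(round(t_out * a$fs + 0.5), 1L), length(a$labels))
  annotation(a$labels[idx], fs_out)
}

#' Check that an annotation and a record describe the same stretch of time
#' @noRd
check_aligned <- function(record, a) {
  if (abs(duration_s(record) - duration_s(a)) > 0.5 / min(record$fs, a$fs))
    stop("annotation duration does not match record duration")
  invisible(TRUE)
}
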