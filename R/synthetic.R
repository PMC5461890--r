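# Synthetic discontinuous (trace discontinu) EEG: alternating burst and
# inter-burst segments with right-skewed (log-normal) durations, a coloured-
# noise background whose log-log spectrum is near linear during inter-bursts,
# and extra broadband 3-15 Hz power during bursts. Ground truth and simulated
# annotator pairs make every pipeline stage testable without clinical data.

#' Synthetic-record configuration
#'
#' Defaults emulate the duration statistics reported for very preterm EEG
#' (median burst 5.7 s, median inter-burst 4.1 s, right-skewed) and the
#' near-linear log-log inter-burst spectrum.
#'
#' @param fs sampling rate in Hz.
#' @param duration_s record length in seconds (>= 30).
#' @param burst_median_s,ibi_median_s log-normal duration medians (s).
#' @param duration_sigma log-space standard deviation of durations.
#' @param burst_gain burst/inter-burst background amplitude ratio (>= 1).
#' @param interburst_slope target log-log spectral exponent of the background.
#' @param burst_bump extra 3-15 Hz power during bursts, relative to the burst
#'   background power; the default 0.15 keeps the mid-band burst-to-inter-burst
#'   spectral ratio close to the modest excess seen in real preterm EEG while
#'   still bending the burst log-log spectrum away from a straight line.
#' @param noise_floor_uv inter-burst RMS amplitude in microvolts.
#' @param seed RNG seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(fs = 256, duration_s = 600,
                             burst_median_s = 5.7, ibi_median_s = 4.1,
                             duration_sigma = 0.75, burst_gain = 3,
                             interburst_slope = -2, burst_bump = 0.15,
                             noise_floor_uv = 10, seed = 1) {
  cfg <- list(fs = fs, duration_s = duration_s,
              burst_median_s = burst_median_s, ibi_median_s = ibi_median_s,
              duration_sigma = duration_sigma, burst_gain = burst_gain,
              interburst_slope = interburst_slope, burst_bump = burst_bump,
              noise_floor_uv = noise_floor_uv, seed = seed)
  stopifnot(fs > 0, duration_s >= 30, burst_median_s > 0, ibi_median_s > 0,
            duration_sigma > 0, burst_gain >= 1, burst_bump >= 0,
            noise_floor_uv > 0)
  structure(cfg, class = "synthetic_config")
}

#' Coloured (power-law) Gaussian noise
#'
#' Spectral shaping of white Gaussian noise so the power spectrum follows
#' `f^exponent`, normalised to unit variance.
#'
#' @param n samples.
#' @param fs sampling rate (Hz).
#' @param exponent log-log spectral slope (e.g. -2).
#' @return numeric vector of length `n`.
#' @export
coloured_noise <- function(n, fs, exponent) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  g <- ifelse(f <= 0, 0, f^(exponent / 2))
  x <- Re(stats::fft(W * g, inverse = TRUE) / n)
  as.numeric(scale(x))
}

# alternating burst/inter-burst segment table covering duration_s
draw_segments <- function(cfg) {
  segs <- data.frame()
  total <- 0
  state <- stats::runif(1) < 0.5             # random starting class
  while (total < cfg$duration_s) {
    med <- if (state) cfg$burst_median_s else cfg$ibi_median_s
    d <- stats::rlnorm(1, meanlog = log(med), sdlog = cfg$duration_sigma)
    segs <- rbind(segs, data.frame(start = total, end = total + d,
                                   burst = state))
    total <- total + d
    state <- !state
  }
  segs$end[nrow(segs)] <- cfg$duration_s
  segs
}

#' Generate a synthetic discontinuous EEG record with ground truth
#'
#' One continuous coloured-noise background is modulated by a burst gain
#' envelope (raised-cosine cross-fades over 0.25 s avoid step artefacts that
#' would trivially cue a detector); bursts additionally receive a 3-15 Hz
#' band-limited component scaled by `burst_bump`. The null construction
#' (`burst_gain = 1`, `burst_bump = 0`) makes bursts and inter-bursts
#' statistically identical.
#'
#' @param config a [synthetic_config()].
#' @return list with `record` (an `eeg_record`, one channel) and
#'   `annotation` (ground truth at `fs`).
#' @export
generate_record <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration_s * fs)
  segs <- draw_segments(config)

  # crossfaded 0/1 burst indicator envelope
  t <- (seq_len(n) - 0.5) / fs
  env <- numeric(n)
  for (j in seq_len(nrow(segs))) {
    if (!segs$burst[j]) next
    env <- env + stats::plogis((t - segs$start[j]) / 0.05) *
      stats::plogis((segs$end[j] - t) / 0.05)
  }
  env <- pmin(env, 1)                        # logistic edges: ~0.25 s 10-90%

  bg <- coloured_noise(n, fs, config$interburst_slope) * config$noise_floor_uv
  gain <- 1 + (config$burst_gain - 1) * env
  x <- bg * gain
  if (config$burst_bump > 0) {
    bump <- bandpass(coloured_noise(n, fs, 0), fs, c(3, 15))
    bump <- bump / stats::sd(bump) *
      sqrt(config$burst_bump) * config$burst_gain * config$noise_floor_uv
    x <- x + bump * env
  }
  labels <- as.integer(env >= 0.5)
  list(record = eeg_record(matrix(x, 1), fs, "C3-C4synth"),
       annotation = annotation(labels, fs))
}

#' Simulate a pair of imperfect annotators from ground truth
#'
#' Each annotator is an independently corrupted copy of the truth: segment
#' boundaries jittered by zero-mean Gaussian noise and whole segments flipped
#' with probability `flip_rate`. With zero jitter and zero flip rate both
#' annotators equal the truth.
#'
#' @param truth ground-truth `annotation`.
#' @param boundary_jitter_s SD of boundary jitter in seconds (>= 0).
#' @param flip_rate per-segment label-flip probability in `[0, 0.5)`.
#' @param seed RNG seed.
#' @return list of two `annotation`s.
#' @export
generate_annotator_pair <- function(truth, boundary_jitter_s = 0.25,
                                    flip_rate = 0.05, seed = 1) {
  stopifnot(inherits(truth, "annotation"),
            boundary_jitter_s >= 0, flip_rate >= 0, flip_rate < 0.5)
  set.seed(seed)
  corrupt <- function() {
    runs <- annotation_runs(truth)
    k <- nrow(runs)
    bounds <- runs$end_s
    if (k > 1) {
      inner <- bounds[-k] + stats::rnorm(k - 1, 0, boundary_jitter_s)
      inner <- pmin(pmax(inner, 0), duration_s(truth))
      inner <- cummax(inner)                 # keep boundaries ordered
      bounds <- c(inner, bounds[k])
    }
    starts <- c(0, bounds[-k])
    lab <- runs$label
    flip <- stats::runif(k) < flip_rate
    lab[flip & !is.na(lab)] <- 1L - lab[flip & !is.na(lab)]
    iv <- data.frame(start_s = starts, end_s = bounds,
                     label = label_names(lab))
    iv <- iv[iv$end_s > iv$start_s & iv$label != "undefined", , drop = FALSE]
    intervals_to_annotation(iv, truth$fs, duration_s(truth))
  }
  list(corrupt(), corrupt())
}
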