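# Band-limiting and auxiliary DSP used by the feature extractors.
#
# IIR filters are applied zero-phase (forward-backwards) through a cascade of
# second-order sections. Direct-form application of the 10th-order band-pass
# polynomials is numerically ill-conditioned at the very low normalised
# frequencies used here (0.5 Hz at 64 Hz), so the designed filter is
# factorised into biquads; transients are settled on a constant pad whose
# length adapts to the slowest pole before the signal is filtered.

# split roots into conjugate pairs / real pairs; near-real roots on the unit
# circle (Butterworth zeros recovered from a noisy 10th-degree polynomial)
# are snapped to exactly +/-1 so band edges keep exact nulls
group_roots <- function(r) {
  is_real <- abs(Im(r)) < 1e-3
  real <- Re(r[is_real])
  snap <- abs(abs(real) - 1) < 1e-2
  real[snap] <- sign(real[snap])
  cplx <- r[!is_real]
  pairs <- list()
  up <- cplx[Im(cplx) > 0]
  dn <- cplx[Im(cplx) < 0]
  for (u in up) {
    j <- which.min(Mod(dn - Conj(u)))
    pairs <- c(pairs, list(c(u, dn[j])))
    dn <- dn[-j]
  }
  pos <- sort(real[real > 0], decreasing = TRUE)
  neg <- sort(real[real <= 0])
  while (length(pos) && length(neg)) {   # band-pass: one null at DC and one
    pairs <- c(pairs, list(c(pos[1], neg[1])))  # at Nyquist per section
    pos <- pos[-1]; neg <- neg[-1]
  }
  rest <- c(pos, neg)
  while (length(rest) >= 2) {
    pairs <- c(pairs, list(rest[1:2])); rest <- rest[-(1:2)]
  }
  if (length(rest)) pairs <- c(pairs, list(rest[1]))
  pairs
}

# factor an Arma design into second-order sections (poles nearest the unit
# circle first, each matched with the nearest zero pair)
sos_design <- function(filt) {
  zpg <- signal::as.Zpg(filt)
  pp <- group_roots(zpg$pole)
  zz <- group_roots(zpg$zero)
  pp <- pp[order(-vapply(pp, function(q) max(Mod(q)), 0))]
  secs <- vector("list", length(pp))
  for (i in seq_along(pp)) {
    q <- pp[[i]]
    w <- numeric(0)
    if (length(zz)) {
      d <- vapply(zz, function(z0) min(Mod(z0[1] - q[1]), Mod(z0[1] - q[length(q)])), 0)
      w <- zz[[which.min(d)]]
      zz <- zz[-which.min(d)]
    }
    b <- Re(signal::poly(w))
    a <- Re(signal::poly(q))
    if (length(b) < length(a)) b <- c(b, rep(0, length(a) - length(b)))
    secs[[i]] <- list(b = b, a = a,
                      pole_r = max(Mod(q)))
  }
  secs[[1]]$b <- secs[[1]]$b * zpg$gain
  secs
}

sos_apply <- function(secs, x) {
  for (s in secs) x <- as.numeric(signal::filter(s$b, s$a, x))
  x
}

# zero-phase filtering: odd-reflection edge padding plus a constant settle
# pad long enough for the slowest pole's transient to decay below 1e-16
zerophase_filter <- function(secs, x) {
  n <- length(x)
  r <- min(max(vapply(secs, `[[`, 0, "pole_r")), 1 - 1e-9)
  K <- min(ceiling(-37 / log(r)), 200000L)
  p <- min(n - 1, 32)
  xx <- if (p > 0) {
    c(2 * x[1] - rev(x[2:(p + 1)]), x, 2 * x[n] - rev(x[(n - p):(n - 1)]))
  } else x
  xx <- c(rep(xx[1], K), xx, rep(xx[length(xx)], K))
  y <- sos_apply(secs, xx)
  y <- rev(sos_apply(secs, rev(y)))
  y[(K + p + 1):(K + p + n)]
}

#' Zero-phase Butterworth bandpass
#'
#' 5th-order Butterworth design applied forward-backwards (zero phase) as a
#' second-order-section cascade with transient settling, so DC is fully
#' rejected and the output is time-reversal symmetric to machine precision.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param band `c(low_hz, high_hz)`, inside `(0, fs/2)`.
#' @param order filter order (default 5).
#' @return filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, band, order = 5) {
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop(sprintf("band (%g, %g) Hz must lie inside (0, %g) Hz", band[1], band[2], fs / 2))
  if (length(x) < 3 * 2 * order)
    stop("signal too short for filter warm-up")
  zerophase_filter(sos_design(signal::butter(order, band / (fs / 2),
                                             type = "pass")), x)
}

# 0.5-10 Hz (NLEO/EDO) or 1-20 Hz (line length) pre-filter for the
# frequency-weighted energy measures: 1st-order Butterworth high-pass plus
# 6th-order elliptic low-pass (0.5 dB passband ripple, 50 dB stopband).
fwe_prefilter <- function(x, fs, band = c(0.5, 10)) {
  hp <- sos_design(signal::butter(1, band[1] / (fs / 2), type = "high"))
  lp <- sos_design(signal::ellip(6, 0.5, 50, band[2] / (fs / 2), type = "low"))
  zerophase_filter(lp, zerophase_filter(hp, x))
}

# centred moving average of a given duration in seconds
moving_average <- function(x, fs, dur_s) {
  w <- max(1L, round(dur_s * fs))
  k <- rep(1 / w, w)
  y <- stats::filter(x, k, sides = 2)
  y <- as.numeric(y)
  # fill edge NAs with nearest computed value
  ok <- which(!is.na(y))
  if (!length(ok)) return(rep(mean(x), length(x)))
  y[seq_len(ok[1] - 1)] <- y[ok[1]]
  if (ok[length(ok)] < length(y))
    y[(ok[length(ok)] + 1):length(y)] <- y[ok[length(ok)]]
  y
}

#' Analytic signal via the FFT
#'
#' Returns `z(n) = x(n) + j H[x(n)]` using the one-sided spectrum
#' construction (DC and Nyquist bins kept, positive frequencies doubled).
#'
#' @param x real signal.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# discrete Hilbert transform h(n) = IDFT{-j sgn(N/2 - k) sgn(k) X(k)}
discrete_hilbert <- function(x) {
  Im(analytic_signal(x))
}

# anti-alias low-pass (zero-phase Butterworth below the target Nyquist) then
# decimate by an integer factor
downsample <- function(x, fs, fs_out) {
  q <- fs / fs_out
  if (abs(q - round(q)) > 1e-9) stop("fs must be an integer multiple of fs_out")
  q <- as.integer(round(q))
  if (q == 1L) return(x)
  lp <- sos_design(signal::butter(6, (0.9 * fs_out / 2) / (fs / 2),
                                  type = "low"))
  y <- zerophase_filter(lp, x)
  y[seq(1L, length(y), by = q)]
}

#' Short-time framing with overlap
#'
#' Slides a window of `window_s` seconds with 75% overlap (hop =
#' `window_s / 4`) across a signal and applies `fun` to each full window.
#'
#' @param x signal.
#' @param fs sampling rate of `x` in Hz.
#' @param window_s window length in seconds.
#' @param fun function of one window returning a scalar (or vector; vectors
#'   are returned as rows).
#' @param overlap fractional overlap between consecutive windows.
#' @return list with `values` (per-window results), `centers_s` (window centre
#'   times in seconds) and `n_windows`.
#' @export
short_time_frame <- function(x, fs, window_s, fun, overlap = 0.75) {
  wlen <- round(window_s * fs)
  hop <- round(wlen * (1 - overlap))
  if (length(x) < wlen) stop("record shorter than one analysis window")
  starts <- seq(1L, length(x) - wlen + 1L, by = hop)
  vals <- lapply(starts, function(s) fun(x[s:(s + wlen - 1L)]))
  values <- if (length(vals[[1]]) > 1L) do.call(rbind, vals) else unlist(vals)
  list(values = values,
       centers_s = (starts - 1L + wlen / 2) / fs,
       n_windows = length(starts))
}

# expand per-window values to a uniform per-sample grid: each output sample
# takes the value of the window whose centre is nearest (piecewise-constant
# hold over the central hop, nearest-value padding at the record edges)
expand_to_grid <- function(values, centers_s, n_out, fs_out = 64) {
  t_out <- (seq_len(n_out) - 0.5) / fs_out
  mids <- (centers_s[-1] + centers_s[-length(centers_s)]) / 2
  idx <- findInterval(t_out, mids) + 1L
  if (is.matrix(values)) values[idx, , drop = FALSE] else values[idx]
}

#' Welch averaged-periodogram PSD
#'
#' Hamming-windowed segments with 50% overlap; used for cohort-style spectral
#' summaries of synthetic records.
#'
#' @param x signal.
#' @param fs sampling rate (Hz).
#' @param window_s segment length in seconds (default 2).
#' @return list with `freq` (Hz) and `psd` (power per bin).
#' @export
welch_psd <- function(x, fs, window_s = 2) {
  wlen <- round(window_s * fs)
  hop <- wlen %/% 2L
  if (length(x) < wlen) stop("signal shorter than one Welch segment")
  w <- signal::hamming(wlen)
  starts <- seq(1L, length(x) - wlen + 1L, by = hop)
  acc <- numeric(wlen %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + wlen - 1L)] * w
    P <- Mod(stats::fft(seg))^2
    acc <- acc + P[seq_len(length(acc))]
  }
  list(freq = (seq_along(acc) - 1L) * fs / wlen, psd = acc / length(starts))
}
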