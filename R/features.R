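# Feature operators: amplitude (envelope), spectral shape (relative band
# power, log-log PSD fit, mean / instantaneous frequency, Higuchi fractal
# dimension) and frequency-weighted energy (EDO, with NLEO and line length as
# reference baselines). All per-sample features share a 64 Hz grid.

#' Default analysis frequency bands
#'
#' Band 1: 0.5-3 Hz, band 2: 3-8 Hz, band 3: 8-15 Hz, band 4: 15-30 Hz;
#' they tile the total analysis band 0.5-30 Hz contiguously.
#'
#' @return list with `bands` (list of `c(low, high)`) and `total_band`.
#' @export
default_bands <- function() {
  list(bands = list(c(0.5, 3), c(3, 8), c(8, 15), c(15, 30)),
       total_band = c(0.5, 30))
}

# squared-magnitude DFT of a window plus the bin frequencies f_k = k*fs/N
psd_bins <- function(x, fs) {
  N <- length(x)
  X <- stats::fft(x)
  k <- 0:(N %/% 2)
  list(S = Mod(X[k + 1])^2, f = k * fs / N, N = N)
}

in_band <- function(f, band) f >= band[1] & f < band[2]   # half-open tiling

#' Signal envelope (squared magnitude of the analytic signal)
#'
#' `a(n) = |z(n)|^2 = |x(n) + j H[x(n)]|^2`; for a pure tone of amplitude A
#' the envelope is constant at A^2.
#'
#' @param x_band band-filtered signal.
#' @return non-negative vector of the same length.
#' @export
envelope <- function(x_band) {
  Mod(analytic_signal(x_band))^2
}

#' Relative spectral power of a band
#'
#' `P_i = sum_{k in band} |X(k)|^2 / P_total` with `P_total` the power over
#' the total analysis band (default 0.5-30 Hz). Band membership is half-open
#' (`low <= f_k < high`) so the four default bands never double-count a bin.
#'
#' @param x analysis window (raw, not band-filtered).
#' @param fs sampling rate (Hz).
#' @param band `c(low, high)` in Hz.
#' @param total_band total normalisation band in Hz.
#' @return `P_i` in `[0, 1]`; an all-zero window returns 0.
#' @export
relative_psd_power <- function(x, fs, band, total_band = c(0.5, 30)) {
  p <- psd_bins(x, fs)
  tot <- sum(p$S[in_band(p$f, total_band)])
  if (tot == 0) return(0)
  sum(p$S[in_band(p$f, band)]) / tot
}

#' Log-log PSD line fit (slope and r-squared)
#'
#' Ordinary least squares of `log |X(k)|^2` on `log f_k` over the in-band DFT
#' bins; returns the slope and the coefficient of determination. A perfectly
#' flat in-band spectrum has zero residual and zero total variance; r^2 is
#' reported as 1 (perfect fit by a constant line) in that degenerate case.
#'
#' @inheritParams relative_psd_power
#' @return named vector `c(slope =, r_squared =)`.
#' @export
loglog_psd_fit <- function(x, fs, band) {
  p <- psd_bins(x, fs)
  sel <- in_band(p$f, band) & p$f > 0
  if (sum(sel) < 3)
    stop(sprintf("fewer than 3 DFT bins in band (%g, %g) Hz for a %.3g s window",
                 band[1], band[2], length(x) / fs))
  S <- pmax(p$S[sel], 1e-300)
  Y <- log(S)
  lf <- log(p$f[sel])
  mx <- mean(lf); my <- mean(Y)
  sxx <- sum((lf - mx)^2)
  slope <- sum((lf - mx) * (Y - my)) / sxx
  Yhat <- my + slope * (lf - mx)
  ss_tot <- sum((Y - my)^2)
  ss_res <- sum((Y - Yhat)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  c(slope = slope, r_squared = r2)
}

#' Periodic (circular) mean frequency of a window
#'
#' Circular mean of the one-sided power spectrum, with the half-spectrum
#' `k = 0 .. N/2 - 1` mapped onto the full circle so that a pure tone
#' recovers its own frequency:
#' `M = fs/(4*pi) * (arg[sum_k |X(k)|^2 e^{j 4 pi k / N}] mod 2*pi)`.
#'
#' @param x_band band-filtered analysis window.
#' @param fs sampling rate (Hz).
#' @return mean frequency in `[0, fs/2]` Hz; `NA` for an all-zero window.
#' @export
mean_frequency <- function(x_band, fs) {
  N <- length(x_band)
  X <- stats::fft(x_band)
  k <- 0:(N %/% 2 - 1)
  S <- Mod(X[k + 1])^2
  if (sum(S) == 0) return(NA_real_)
  C <- sum(S * exp(1i * 4 * pi * k / N))
  ang <- Arg(C) %% (2 * pi)
  fs / (4 * pi) * ang
}

#' Instantaneous frequency (central finite difference of the analytic phase)
#'
#' `f(n) = fs/(4*pi) * ((phi(n+1) - phi(n-1)) mod 2*pi)` with
#' `phi(n) = arg z(n)`. Edge samples replicate their nearest interior value.
#'
#' @param x_band band-filtered signal, length >= 3.
#' @param fs sampling rate (Hz).
#' @return per-sample frequency in Hz, same length as input.
#' @export
instantaneous_frequency <- function(x_band, fs) {
  n <- length(x_band)
  if (n < 3) stop("need at least 3 samples")
  phi <- Arg(analytic_signal(x_band))
  d <- (phi[3:n] - phi[1:(n - 2)]) %% (2 * pi)
  f <- fs / (4 * pi) * d
  c(f[1], f, f[length(f)])
}

#' Higuchi fractal dimension
#'
#' Curve lengths `L_m(k)` are averaged over offsets m for each scale
#' `k = 1..k_max`; the negated slope of `log L(k)` on `log k` estimates the
#' fractal dimension D (1 for a smooth line, approaching 2 for uncorrelated
#' noise).
#'
#' @param x analysis window (broadband 0.5-30 Hz filtered in the pipeline).
#' @param k_max largest scale (default 8 for 1 s windows at 64 Hz).
#' @return D estimate; `NA` for a constant window.
#' @export
higuchi_fd <- function(x, k_max = 8) {
  N <- length(x)
  if (N < 2 * k_max) stop("window too short for k_max")
  Lk <- vapply(seq_len(k_max), function(k) {
    Lm <- vapply(seq_len(k), function(m) {
      nmax <- (N - m) %/% k
      if (nmax < 1) return(NA_real_)
      idx <- m + (0:nmax) * k
      sum(abs(diff(x[idx]))) * (N - 1) / (nmax * k^2)
    }, 0)
    mean(Lm, na.rm = TRUE)
  }, 0)
  if (any(Lk <= 0)) return(NA_real_)
  lk <- log(seq_len(k_max)); ll <- log(Lk)
  -sum((lk - mean(lk)) * (ll - mean(ll))) / sum((lk - mean(lk))^2)
}

# raw NLEO pointwise term psi(n) = x(n-1)x(n-2) - x(n)x(n-3), n = 4..N
# (1-based); edges replicate the first computed value
nleo_core <- function(x) {
  N <- length(x)
  if (N < 4) stop("need at least 4 samples")
  psi <- x[3:(N - 1)] * x[2:(N - 2)] - x[4:N] * x[1:(N - 3)]
  c(rep(psi[1], 3), psi)
}

#' Nonlinear energy operator (NLEO) per-sample stream
#'
#' Absolute value of the pointwise quadratic term
#' `x(n-1)x(n-2) - x(n)x(n-3)`; the detection baseline applies a 0.5-10 Hz
#' pre-filter and a 1.5 s moving average on top (see [nleo_stream()]).
#'
#' @param x signal (at the acquisition rate).
#' @return non-negative vector, same length as `x`.
#' @export
nleo <- function(x) {
  abs(nleo_core(x))
}

#' Line length of a window
#'
#' `l = sum |x(n+1) - x(n)|`, a frequency-weighted energy proxy.
#'
#' @param x window, length >= 2.
#' @return scalar `l >= 0`.
#' @export
line_length <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  sum(abs(diff(x)))
}

#' Envelope-derivative operator (EDO)
#'
#' Non-negative frequency-weighted energy operator built from the analytic
#' signal: `Gamma(n) = 1/4 [(x(n+1) - x(n-1))^2 + (h(n+1) - h(n-1))^2]`,
#' where `h(n)` is the discrete Hilbert transform of `x`. A pure tone
#' `A cos(w n)` yields the constant `A^2 sin^2(w)`, so the operator vanishes
#' at DC and weights energy by frequency. `cross_sign = "printed"` selects the
#' sign variant that adds the cross terms instead (maximal response at DC),
#' kept for comparison only.
#'
#' @param x signal (at the acquisition rate), length >= 3.
#' @param cross_sign `"subtract"` (default, non-negative) or `"printed"`.
#' @return per-sample energy, same length as `x`; edge samples replicate.
#' @export
edo <- function(x, cross_sign = c("subtract", "printed")) {
  cross_sign <- match.arg(cross_sign)
  n <- length(x)
  if (n < 3) stop("need at least 3 samples")
  h <- discrete_hilbert(x)
  xp <- x[3:n]; xm <- x[1:(n - 2)]
  hp <- h[3:n]; hm <- h[1:(n - 2)]
  g <- if (cross_sign == "subtract") {
    ((xp - xm)^2 + (hp - hm)^2) / 4
  } else {
    (xp^2 + xm^2 + hp^2 + hm^2) / 4 + (xp * xm + hp * hm) / 2
  }
  c(g[1], g, g[length(g)])
}

# ---- frequency-weighted energy baselines at the acquisition rate ----------
# Each: pre-filter, operator, moving average, then decimation to 64 Hz.

#' @rdname nleo
#' @param fs acquisition sampling rate (Hz), e.g. 256.
#' @export
nleo_stream <- function(x, fs) {
  y <- abs(nleo_core(fwe_prefilter(x, fs, c(0.5, 10))))
  downsample(moving_average(y, fs, 1.5), fs, 64)
}

#' @rdname line_length
#' @param fs acquisition sampling rate (Hz).
#' @export
line_length_stream <- function(x, fs) {
  xb <- fwe_prefilter(x, fs, c(1, 20))
  d <- abs(diff(xb))
  y <- c(d[1], d)
  downsample(moving_average(y, fs, 1), fs, 64)
}

#' @rdname edo
#' @param fs acquisition sampling rate (Hz).
#' @export
edo_stream <- function(x, fs, cross_sign = "subtract") {
  y <- edo(fwe_prefilter(x, fs, c(0.5, 10)), cross_sign)
  downsample(moving_average(y, fs, 1.5), fs, 64)
}

# ---- feature set ----------------------------------------------------------

#' The default 26-member feature set
#'
#' One envelope-derivative operator feature, one Higuchi fractal dimension,
#' and envelope, relative PSD power, mean frequency, instantaneous frequency,
#' log-log PSD slope and log-log PSD r^2 in each of the four analysis bands.
#' Amplitude and fractal-dimension features use 1 s analysis windows,
#' spectral features 2 s; envelope and instantaneous frequency are summarised
#' by the window median. EDO, envelope and relative-power features are
#' natural-log transformed before z-scoring.
#'
#' @return data.frame with columns `name`, `feature`, `band`, `window_s`,
#'   `summary`, `log_transformed`.
#' @export
feature_specs <- function() {
  band4 <- function(feature, window_s, summary, log_tr) {
    data.frame(name = paste0(feature, "_b", 1:4), feature = feature,
               band = 1:4, window_s = window_s, summary = summary,
               log_transformed = log_tr, stringsAsFactors = FALSE)
  }
  rbind(
    data.frame(name = "edo", feature = "edo", band = NA_integer_,
               window_s = NA_real_, summary = "stream", log_transformed = TRUE),
    data.frame(name = "fd", feature = "fd", band = NA_integer_,
               window_s = 1, summary = "scalar", log_transformed = FALSE),
    band4("env", 1, "median", TRUE),
    band4("rpsd", 2, "scalar", TRUE),
    band4("mf", 2, "scalar", FALSE),
    band4("if", 2, "median", FALSE),
    band4("slope", 2, "scalar", FALSE),
    band4("r2", 2, "scalar", FALSE)
  )
}

#' Compute the per-sample feature matrix for one channel
#'
#' Extracts all 26 features on a uniform 64 Hz grid. The EDO is computed at
#' the acquisition rate (energy operators are sensitive to sampling rate) and
#' decimated after its 1.5 s moving average; all other features are computed
#' on the 64 Hz signal within short-time windows (75% overlap) and expanded
#' to the grid by piecewise-constant hold.
#'
#' @param record an `eeg_record`.
#' @param channel channel index or label (default first channel).
#' @param k_max Higuchi scale limit.
#' @param bands band set from [default_bands()].
#' @return a `feature_matrix`: list with `values` (samples x 26), `specs`,
#'   `fs = 64`, `transformed = FALSE`.
#' @export
compute_features <- function(record, channel = 1, k_max = 8,
                             bands = default_bands()) {
  stopifnot(inherits(record, "eeg_record"))
  if (is.character(channel)) channel <- match(channel, record$channel_labels)
  x <- record$samples[channel, ]
  fs <- record$fs
  x64 <- if (fs == 64) x else downsample(x, fs, 64)
  n64 <- length(x64)
  specs <- feature_specs()
  vals <- matrix(NA_real_, n64, nrow(specs), dimnames = list(NULL, specs$name))

  vals[, "edo"] <- edo_stream(x, fs)[seq_len(n64)]

  xb_broad <- bandpass(x64, 64, bands$total_band)
  fr <- short_time_frame(xb_broad, 64, 1, function(w) {
    d <- higuchi_fd(w, k_max)
    if (is.na(d)) 1 else d
  })
  vals[, "fd"] <- expand_to_grid(fr$values, fr$centers_s, n64)

  # spectral features from the raw 64 Hz signal in 2 s windows
  fr2 <- short_time_frame(x64, 64, 2, function(w) {
    out <- numeric(12)
    for (i in 1:4) {
      out[i] <- relative_psd_power(w, 64, bands$bands[[i]], bands$total_band)
      ll <- loglog_psd_fit(w, 64, bands$bands[[i]])
      out[4 + i] <- ll["slope"]
      out[8 + i] <- ll["r_squared"]
    }
    out
  })
  sp <- expand_to_grid(fr2$values, fr2$centers_s, n64)
  vals[, paste0("rpsd_b", 1:4)] <- sp[, 1:4]
  vals[, paste0("slope_b", 1:4)] <- sp[, 5:8]
  vals[, paste0("r2_b", 1:4)] <- sp[, 9:12]

  for (i in 1:4) {
    xb <- bandpass(x64, 64, bands$bands[[i]])
    env <- envelope(xb)
    fe <- short_time_frame(env, 64, 1, stats::median)
    vals[, paste0("env_b", i)] <- expand_to_grid(fe$values, fe$centers_s, n64)
    inst <- instantaneous_frequency(xb, 64)
    fi <- short_time_frame(inst, 64, 2, stats::median)
    vals[, paste0("if_b", i)] <- expand_to_grid(fi$values, fi$centers_s, n64)
    fm <- short_time_frame(xb, 64, 2, function(w) {
      m <- mean_frequency(w, 64)
      if (is.na(m)) mean(bands$bands[[i]]) else m
    })
    vals[, paste0("mf_b", i)] <- expand_to_grid(fm$values, fm$centers_s, n64)
  }

  structure(list(values = vals, specs = specs, fs = 64,
                 transformed = FALSE, stats = NULL),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features @ %g Hz (%s)\n",
              nrow(x$values), ncol(x$values), x$fs,
              if (x$transformed) "log/z-scored" else "raw"))
  invisible(x)
}

#' Log-transform and z-score a feature matrix
#'
#' Applies the natural log to heavy-tailed energy features (EDO, envelopes,
#' relative band powers; values floored at 1e-12 first) and normalises every
#' column to z-scores. When `stats` is supplied (from a training set) its
#' per-feature mean/sd are applied unchanged, so test records are scored on
#' the training scale.
#'
#' @param fm a raw `feature_matrix`.
#' @param stats optional list with `mean` and `sd` vectors (one per feature)
#'   estimated on training data.
#' @return a transformed `feature_matrix` carrying `stats`.
#' @export
transform_and_zscore <- function(fm, stats = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$transformed) stop("feature matrix already transformed")
  v <- fm$values
  logcols <- fm$specs$name[fm$specs$log_transformed]
  v[, logcols] <- log(pmax(v[, logcols, drop = FALSE], 1e-12))
  if (is.null(stats)) {
    mu <- colMeans(v)
    sdv <- apply(v, 2, stats::sd)
    if (any(sdv == 0))
      stop("zero-variance feature column(s): ",
           paste(colnames(v)[sdv == 0], collapse = ", "))
    stats <- list(mean = mu, sd = sdv)
  }
  v <- sweep(sweep(v, 2, stats$mean), 2, stats$sd, "/")
  out <- fm
  out$values <- v
  out$transformed <- TRUE
  out$stats <- stats
  out
}

#' Write a feature matrix to CSV (one row per 64 Hz sample)
#' @param fm a `feature_matrix`.
#' @param path output path.
#' @export
write_feature_csv <- function(fm, path) {
  utils::write.csv(as.data.frame(fm$values), path, row.names = FALSE)
  invisible(path)
}
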