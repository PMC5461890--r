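# Feature operators against analytic cases and their brute-force oracles.

test_that("bandpass rejects DC, passes the band centre, and is zero-phase", {
  fs <- 64
  # constant 10 uV offset through the lowest band leaves no DC
  y <- bandpass(rep(10, 4 * fs), fs, c(0.5, 3))
  expect_lt(abs(mean(y)), 1e-6 * 10)
  # band-centre tone passes at unit gain (compare RMS on the middle half)
  tone <- make_tone(5.5, fs, 8)
  yt <- bandpass(tone, fs, c(3, 8))
  mid <- seq(round(length(tone) * 0.25), round(length(tone) * 0.75))
  expect_equal(sqrt(mean(yt[mid]^2)), sqrt(mean(tone[mid]^2)),
               tolerance = 0.01)
  # forward-backward filtering: time-reversed input gives time-reversed output
  set.seed(2)
  z <- rnorm(512)
  expect_lt(max(abs(rev(bandpass(rev(z), fs, c(3, 8))) -
                    bandpass(z, fs, c(3, 8)))), 1e-9)
  expect_error(bandpass(z, fs, c(3, 40)), "band")
})

test_that("envelope of a pure tone is the squared amplitude", {
  fs <- 64
  x <- make_tone(5.5, fs, 4, amp = 3)
  a <- envelope(x)
  mid <- seq(round(length(x) * 0.2), round(length(x) * 0.8))
  expect_true(all(abs(a[mid] - 9) / 9 < 0.01))
  expect_equal(envelope(rep(0, 128)), rep(0, 128))
})

test_that("envelope tracks a slow amplitude modulation", {
  fs <- 64
  t <- (0:(8 * fs - 1)) / fs
  amp <- 1 + 0.5 * sin(2 * pi * 0.25 * t)
  x <- amp * sin(2 * pi * 8 * t)
  a <- envelope(x)
  mid <- seq(round(length(x) * 0.2), round(length(x) * 0.8))
  expect_true(all(abs(a[mid] - amp[mid]^2) / amp[mid]^2 < 0.05))
})

test_that("relative band power concentrates on the tone's band and tiles to 1", {
  fs <- 64
  bands <- default_bands()
  x <- make_tone(5, fs, 2)
  p <- vapply(bands$bands, function(b) relative_psd_power(x, fs, b), 0)
  expect_gte(p[2], 0.95)
  expect_true(all(p[-2] <= 0.05))
  # tiling: the four band powers sum to 1 on any non-zero window
  set.seed(4)
  for (i in 1:10) {
    w <- rnorm(128)
    ps <- vapply(bands$bands, function(b) relative_psd_power(w, fs, b), 0)
    expect_equal(sum(ps), 1, tolerance = 1e-6)
  }
  expect_equal(relative_psd_power(rep(0, 128), fs, bands$bands[[1]]), 0)
})

test_that("white-noise band powers approach bandwidth fractions", {
  fs <- 64
  bands <- default_bands()
  set.seed(5)
  p <- replicate(100, {
    w <- rnorm(20 * fs)
    vapply(bands$bands, function(b) relative_psd_power(w, fs, b), 0)
  })
  expected <- vapply(bands$bands, function(b) (b[2] - b[1]) / 29.5, 0)
  expect_true(all(abs(rowMeans(p) - expected) / expected < 0.1))
})

test_that("log-log fit recovers an exact power law and handles flat spectra", {
  fs <- 64
  x <- make_exact_powerlaw_signal(128, -2)
  fit <- loglog_psd_fit(x, fs, c(3, 8))
  expect_equal(unname(fit["slope"]), -2, tolerance = 1e-9)
  expect_equal(unname(fit["r_squared"]), 1, tolerance = 1e-9)
  # flat in-band spectrum: slope 0, degenerate r^2 reported as 1
  xf <- make_exact_powerlaw_signal(128, 0)
  fitf <- loglog_psd_fit(xf, fs, c(3, 8))
  expect_equal(unname(fitf["slope"]), 0, tolerance = 1e-9)
  expect_equal(unname(fitf["r_squared"]), 1)
  expect_error(loglog_psd_fit(make_tone(5, fs, 2), fs, c(0.5, 1)), "bins")
})

test_that("log-log slope of synthetic 1/f^1.5 noise is near -1.5", {
  fs <- 64
  set.seed(6)
  slopes <- replicate(200, {
    x <- coloured_noise(2 * fs, fs, -1.5)
    unname(loglog_psd_fit(x, fs, c(3, 8))["slope"])
  })
  expect_lt(abs(median(slopes) + 1.5), 0.3)
})

test_that("mean frequency recovers tones and symmetric spectra", {
  fs <- 64; N <- 128
  binw <- fs / N
  expect_lt(abs(mean_frequency(make_tone(10, fs, 2), fs) - 10), binw)
  # two equal tones at 9 and 11 Hz average to 10
  two <- make_tone(9, fs, 2) + make_tone(11, fs, 2)
  expect_lt(abs(mean_frequency(two, fs) - 10), binw)
  expect_true(is.na(mean_frequency(rep(0, N), fs)))
  # exactly symmetric two-sided power about 10 Hz (phase-coherent bins)
  expect_lt(abs(mean_frequency(make_tone(8, fs, 2) + make_tone(12, fs, 2),
                               fs) - 10), binw)
})

test_that("instantaneous frequency is exact for tones and sign-invariant", {
  fs <- 64
  x <- make_tone(5, fs, 4)
  f <- instantaneous_frequency(x, fs)
  mid <- seq(round(length(x) * 0.2), round(length(x) * 0.8))
  expect_true(all(abs(f[mid] - 5) < 1e-3))
  expect_equal(instantaneous_frequency(-x, fs), f)
  # linear chirp: median IF over the window sits at mid-chirp
  t <- (0:(4 * fs - 1)) / fs
  chirp <- sin(2 * pi * (2 * t + (8 - 2) / (2 * 4) * t^2))
  expect_lt(abs(median(instantaneous_frequency(chirp, fs)) - 5), 0.5)
})

test_that("Higuchi dimension separates lines, tones and noise", {
  expect_lt(abs(higuchi_fd(seq(0, 1, length.out = 64), 8) - 1), 0.05)
  set.seed(8)
  d_noise <- replicate(100, higuchi_fd(rnorm(64), 8))
  expect_lt(abs(median(d_noise) - 2), 0.15)
  d_sin <- higuchi_fd(make_tone(2, 64, 1), 8)
  expect_gte(d_sin, 1); expect_lte(d_sin, 1.3)
  expect_true(is.na(higuchi_fd(rep(1, 64), 8)))
})

test_that("NLEO vanishes on constants and scales quadratically", {
  expect_equal(nleo(rep(3.7, 100)), rep(0, 100))
  set.seed(9)
  x <- rnorm(100)
  expect_equal(nleo(2 * x), 4 * nleo(x), tolerance = 1e-12)
  # raw operator on a tone is constant and matches direct evaluation
  tone <- make_tone(5, 64, 2)
  v <- nleo(tone)[10:110]
  expect_lt(diff(range(v)), 1e-9)
})

test_that("line length matches its definition", {
  expect_equal(line_length(c(0, 1, 0, 1)), 3)
  expect_equal(line_length(rep(2, 50)), 0)
  set.seed(10)
  x <- rnorm(64)
  expect_equal(line_length(-2.5 * x), 2.5 * line_length(x))
})

test_that("EDO of a tone equals A^2 sin^2(omega) and rises with frequency", {
  fs <- 256
  for (f0 in c(2, 5, 8)) {
    A <- 1.5
    t <- 0:(2 * fs - 1)
    x <- A * cos(2 * pi * f0 / fs * t)
    g <- edo(x)
    mid <- seq(round(length(x) * 0.2), round(length(x) * 0.8))
    expected <- A^2 * sin(2 * pi * f0 / fs)^2
    expect_true(all(abs(g[mid] - expected) / expected < 0.01))
  }
  # monotone frequency weighting below 10 Hz at fixed amplitude
  resp <- vapply(seq(1, 9, by = 2), function(f0) {
    x <- cos(2 * pi * f0 / fs * (0:(2 * fs - 1)))
    median(edo(x))
  }, 0)
  expect_true(all(diff(resp) > 0))
  # DC input is removed by the 0.5-10 Hz pre-filter
  dc <- edo_stream(rep(5, 4 * fs), fs)
  expect_lt(max(abs(dc)), 1e-4)
})

test_that("EDO is non-negative on random signals", {
  set.seed(12)
  for (i in 1:1000) {
    x <- rnorm(sample(64:256, 1))
    expect_gte(min(edo(x)), -1e-12)
  }
})

test_that("printed-sign EDO variant peaks at DC instead", {
  fs <- 256
  x <- cos(2 * pi * 5 / fs * (0:(fs - 1)))
  g <- edo(x, cross_sign = "printed")
  mid <- seq(round(length(x) * 0.2), round(length(x) * 0.8))
  expect_equal(median(g[mid]), cos(2 * pi * 5 / fs)^2, tolerance = 0.01)
})

test_that("short-time framing counts windows and expands correctly", {
  fs <- 64
  x <- rep(1, 10 * fs)
  fr <- short_time_frame(x, fs, 2, mean)
  expect_equal(fr$n_windows, 17)            # floor((10 - 2)/0.5) + 1
  out <- expand_to_grid(fr$values, fr$centers_s, length(x), fs)
  expect_equal(length(out), 10 * 64)        # duration x 64 exactly
  expect_equal(out, rep(1, length(x)))      # constant stays constant
  expect_error(short_time_frame(rep(1, 32), fs, 2, mean), "shorter")
})

test_that("every operator matches its brute-force oracle on random windows", {
  fs <- 64
  set.seed(13)
  bands <- default_bands()
  for (i in 1:25) {
    x <- rnorm(128)                        # 2 s at 64 Hz
    expect_equal(envelope(x), oracle_envelope(x), tolerance = 1e-9)
    b <- bands$bands[[sample(4, 1)]]
    expect_equal(relative_psd_power(x, fs, b),
                 oracle_relative_psd(x, fs, b), tolerance = 1e-9)
    expect_equal(unname(loglog_psd_fit(x, fs, b)),
                 unname(oracle_loglog_fit(x, fs, b)), tolerance = 1e-9)
    expect_equal(mean_frequency(x, fs), oracle_mean_frequency(x, fs),
                 tolerance = 1e-9)
    expect_equal(instantaneous_frequency(x, fs)[2:127],
                 oracle_instfreq(x, fs), tolerance = 1e-9)
    expect_equal(higuchi_fd(x, 8), oracle_higuchi(x, 8), tolerance = 1e-9)
    expect_equal(sum(nleo(x)[4:128]), oracle_nleo_theta(x), tolerance = 1e-9)
    expect_equal(line_length(x), oracle_line_length(x), tolerance = 1e-9)
    expect_equal(edo(x)[2:127], oracle_edo(x), tolerance = 1e-9)
  }
})

test_that("features have the expected amplitude homogeneity", {
  fs <- 64
  set.seed(14)
  x <- rnorm(128)
  a <- 10
  expect_equal(envelope(a * x), a^2 * envelope(x), tolerance = 1e-9)
  expect_equal(nleo(a * x), a^2 * nleo(x), tolerance = 1e-9)
  expect_equal(edo(a * x), a^2 * edo(x), tolerance = 1e-9)
  expect_equal(line_length(a * x), a * line_length(x), tolerance = 1e-9)
  for (b in default_bands()$bands[2:4]) {
    expect_equal(loglog_psd_fit(a * x, fs, b), loglog_psd_fit(x, fs, b),
                 tolerance = 1e-9)
    expect_equal(mean_frequency(a * bandpass(x, fs, b), fs),
                 mean_frequency(bandpass(x, fs, b), fs), tolerance = 1e-9)
  }
  expect_equal(instantaneous_frequency(a * x, fs),
               instantaneous_frequency(x, fs), tolerance = 1e-9)
  expect_equal(higuchi_fd(a * x, 8), higuchi_fd(x, 8), tolerance = 1e-9)
  expect_equal(relative_psd_power(a * x, fs, c(3, 8)),
               relative_psd_power(x, fs, c(3, 8)), tolerance = 1e-9)
})

test_that("the default feature set has 26 members with the stated structure", {
  specs <- feature_specs()
  expect_equal(nrow(specs), 26)
  expect_equal(sum(specs$feature == "env"), 4)
  expect_equal(sum(specs$feature == "rpsd"), 4)
  expect_equal(sum(specs$feature == "mf"), 4)
  expect_equal(sum(specs$feature == "if"), 4)
  expect_equal(sum(specs$feature == "slope"), 4)
  expect_equal(sum(specs$feature == "r2"), 4)
  expect_equal(sum(specs$feature %in% c("edo", "fd")), 2)
  expect_false(anyDuplicated(specs$name) > 0)
  # window structure: spectral features 2 s, amplitude/FD 1 s
  expect_true(all(specs$window_s[specs$feature %in%
                                   c("rpsd", "mf", "if", "slope", "r2")] == 2))
  expect_true(all(specs$window_s[specs$feature %in% c("env", "fd")] == 1))
  # median summaries for envelope and instantaneous frequency
  expect_true(all(specs$summary[specs$feature %in% c("env", "if")] == "median"))
  # log transform set: EDO, envelope, relative power
  expect_setequal(specs$name[specs$log_transformed],
                  c("edo", paste0("env_b", 1:4), paste0("rpsd_b", 1:4)))
})

test_that("compute_features yields a complete NaN-free 64 Hz matrix", {
  g <- generate_record(synthetic_config(duration_s = 30, seed = 21))
  fm <- compute_features(g$record)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(ncol(fm$values), 26)
  expect_equal(nrow(fm$values), 30 * 64)
  expect_false(anyNA(fm$values))
  expect_equal(fm$fs, 64)
})

test_that("z-scoring normalises and applies training stats consistently", {
  g <- generate_record(synthetic_config(duration_s = 30, seed = 22))
  fm <- compute_features(g$record)
  z <- transform_and_zscore(fm)
  expect_true(all(abs(colMeans(z$values)) < 1e-9))
  expect_true(all(abs(apply(z$values, 2, sd) - 1) < 1e-9))
  # applying the training stats back to the same matrix reproduces it
  z2 <- transform_and_zscore(fm, stats = z$stats)
  expect_equal(z2$values, z$values)
  # log of an all-ones envelope column is all zeros, which then trips the
  # zero-variance guard naming the feature
  fm2 <- fm
  fm2$values[, "env_b1"] <- 1
  expect_identical(log(pmax(fm2$values[, "env_b1"], 1e-12)), rep(0, nrow(fm2$values)))
  expect_error(transform_and_zscore(fm2), "env_b1")
  expect_error(transform_and_zscore(z), "already")
})
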