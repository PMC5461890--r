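# Small in-code fixtures shared across test files.

make_tone <- function(freq, fs = 64, dur_s = 2, amp = 1, phase = 0) {
  t <- (0:(round(dur_s * fs) - 1)) / fs
  amp * sin(2 * pi * freq * t + phase)
}

# referential record with named electrodes built from a list of signals
make_referential <- function(signals, fs = 256) {
  eeg_record(do.call(rbind, signals), fs, names(signals))
}

# a small labelled record pair for pipeline tests
make_synth_set <- function(n_records, duration_s, seed0 = 0, ...) {
  recs <- list(); anns <- list()
  for (k in seq_len(n_records)) {
    g <- generate_record(synthetic_config(duration_s = duration_s,
                                          seed = seed0 + k - 1, ...))
    recs[[k]] <- g$record
    anns[[k]] <- g$annotation
  }
  list(records = recs, annotations = anns)
}

# real Hermitian spectrum |X(k)|^2 = k^(-2) over the positive bins
make_exact_powerlaw_signal <- function(N = 128, exponent = -2) {
  X <- complex(N)
  for (k in 1:(N / 2 - 1)) {
    X[k + 1] <- k^(exponent / 2)
    X[N - k + 1] <- Conj(X[k + 1])
  }
  Re(stats::fft(X, inverse = TRUE)) / N
}
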