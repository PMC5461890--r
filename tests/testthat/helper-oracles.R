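# Literal loop-over-definition oracles for the feature operators. These stay
# deliberately naive (direct DFT summation, explicit loops) and independent of
# the package's vectorized implementations.

oracle_dft <- function(x) {
  N <- length(x)
  k <- 0:(N - 1)
  vapply(k, function(kk) {
    sum(x * exp(-2i * pi * kk * (0:(N - 1)) / N))
  }, complex(1))
}

# discrete Hilbert transform h(n) = IDFT{-j sgn(N/2 - k) sgn(k) X(k)}
oracle_hilbert <- function(x) {
  N <- length(x)
  X <- oracle_dft(x)
  k <- 0:(N - 1)
  mult <- -1i * sign(N / 2 - k) * sign(k)
  H <- X * mult
  n <- 0:(N - 1)
  Re(vapply(n, function(nn) {
    sum(H * exp(2i * pi * k * nn / N)) / N
  }, complex(1)))
}

# squared envelope a(n) = |x(n) + j H[x(n)]|^2
oracle_envelope <- function(x) {
  h <- oracle_hilbert(x)
  x^2 + h^2
}

oracle_relative_psd <- function(x, fs, band, total_band = c(0.5, 30)) {
  X <- oracle_dft(x)
  N <- length(x)
  tot <- 0; inb <- 0
  for (k in 0:(N %/% 2)) {
    f <- k * fs / N
    p <- Mod(X[k + 1])^2
    if (f >= total_band[1] && f < total_band[2]) tot <- tot + p
    if (f >= band[1] && f < band[2]) inb <- inb + p
  }
  if (tot == 0) 0 else inb / tot
}

oracle_loglog_fit <- function(x, fs, band) {
  X <- oracle_dft(x)
  N <- length(x)
  fk <- c(); S <- c()
  for (k in 0:(N %/% 2)) {
    f <- k * fs / N
    if (f >= band[1] && f < band[2] && f > 0) {
      fk <- c(fk, f); S <- c(S, max(Mod(X[k + 1])^2, 1e-300))
    }
  }
  fit <- stats::lm(log(S) ~ log(fk))
  Y <- log(S); Yhat <- stats::fitted(fit)
  ss_tot <- sum((Y - mean(Y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum((Y - Yhat)^2) / ss_tot
  c(slope = unname(stats::coef(fit)[2]), r_squared = r2)
}

# circular mean of the one-sided power spectrum, half spectrum on the full
# circle: M = fs/(4 pi) * (arg sum_k |X(k)|^2 e^{j 4 pi k/N} mod 2 pi)
oracle_mean_frequency <- function(x, fs) {
  X <- oracle_dft(x)
  N <- length(x)
  acc <- 0 + 0i
  for (k in 0:(N %/% 2 - 1)) {
    acc <- acc + Mod(X[k + 1])^2 * exp(1i * 4 * pi * k / N)
  }
  fs / (4 * pi) * (Arg(acc) %% (2 * pi))
}

oracle_instfreq <- function(x, fs) {
  h <- oracle_hilbert(x)
  phi <- atan2(h, x)
  N <- length(x)
  f <- numeric(N - 2)
  for (n in 2:(N - 1)) {
    f[n - 1] <- fs / (4 * pi) * ((phi[n + 1] - phi[n - 1]) %% (2 * pi))
  }
  f
}

oracle_higuchi <- function(x, k_max) {
  N <- length(x)
  Lk <- numeric(k_max)
  for (k in 1:k_max) {
    Lm <- numeric(k)
    for (m in 1:k) {
      nmax <- floor((N - m) / k)
      s <- 0
      for (i in 1:nmax) {
        s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      }
      Lm[m] <- s * (N - 1) / (nmax * k^2)
    }
    Lk[k] <- mean(Lm)
  }
  fit <- stats::lm(log(Lk) ~ log(1:k_max))
  -unname(stats::coef(fit)[2])
}

# windowed NLEO sum Theta = sum_n |x(n-1)x(n-2) - x(n)x(n-3)|
oracle_nleo_theta <- function(x) {
  N <- length(x)
  s <- 0
  for (n in 4:N) {
    s <- s + abs(x[n - 1] * x[n - 2] - x[n] * x[n - 3])
  }
  s
}

oracle_line_length <- function(x) {
  s <- 0
  for (n in 1:(length(x) - 1)) s <- s + abs(x[n + 1] - x[n])
  s
}

# printed EDO terms with the cross terms subtracted
oracle_edo <- function(x) {
  h <- oracle_hilbert(x)
  N <- length(x)
  g <- numeric(N - 2)
  for (n in 2:(N - 1)) {
    g[n - 1] <- (x[n + 1]^2 + x[n - 1]^2 + h[n + 1]^2 + h[n - 1]^2) / 4 -
      (x[n + 1] * x[n - 1] + h[n + 1] * h[n - 1]) / 2
  }
  g
}

# pair-counting AUC: concordant pairs + half ties
oracle_auc_paircount <- function(d, y) {
  pos <- d[y == 1]; neg <- d[y == 0]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + (p > q) + 0.5 * (p == q)
  }
  s / (length(pos) * length(neg))
}
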