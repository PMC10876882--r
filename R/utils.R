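# Internal numerical helpers shared across modules.

# Draw from a normal truncated to [lo, hi] by rejection (bounds are a few sd
# from the mean everywhere we use this, so rejection is cheap).
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# Unit-variance Gaussian noise band-limited to [f_lo, f_hi] Hz by hard
# spectral masking.  Returns a zero-mean series of length n at spacing dt.
band_limited_noise <- function(n, dt, f_lo, f_hi) {
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  f <- fft_freqs(n, dt)
  keep <- abs(f) >= f_lo & abs(f) <= f_hi
  xf[!keep] <- 0i
  y <- Re(stats::fft(xf, inverse = TRUE)) / n
  y <- y - mean(y)
  s <- stats::sd(y)
  if (s < .Machine$double.eps) stop("degenerate band-limited noise: empty band")
  y / s
}

# Frequencies (signed) of the length-n DFT at sampling interval dt.
fft_freqs <- function(n, dt) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * dt)
}

# Scale a vector to zero mean, unit sd.
standardize <- function(x) {
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s < .Machine$double.eps) return(x * 0)
  x / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
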