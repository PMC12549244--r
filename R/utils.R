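# Internal numeric helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Sample skewness / excess-free kurtosis (moment definitions, as used by the
# feature extractors; kurtosis is the raw fourth standardized moment).
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(NA_real_)
  mean((x - mean(x))^3) / s^3
}

kurtosis <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) return(NA_real_)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(NA_real_)
  mean((x - mean(x))^4) / s^4
}

# Least-squares slope of a series against time (units of x per second).
series_slope <- function(x, fs) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  t <- (seq_len(n) - 1) / fs
  tc <- t - mean(t)
  sum(tc * (x - mean(x))) / sum(tc^2)
}

# Trapezoidal area under the curve (units of x * seconds).
series_auc <- function(x, fs) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  sum((x[-1] + x[-n]) / 2) / fs
}

rms <- function(x) sqrt(mean(x^2))

# Linear convolution via FFT with power-of-2 padding (stats::convolve pads
# to awkward mixed-radix lengths and can be an order of magnitude slower).
fft_conv <- function(x, k) {
  n <- length(x) + length(k) - 1L
  nn <- stats::nextn(n, 2)
  xf <- fft(c(x, numeric(nn - length(x))))
  kf <- fft(c(k, numeric(nn - length(k))))
  Re(fft(xf * kf, inverse = TRUE))[seq_len(n)] / nn
}

# Deterministic child seeds: fan a master seed out to named sub-streams so any
# stage can be regenerated in isolation.  Kept below 2^31 - 1.
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Welch power spectral density with Hamming windows and 50% overlap.
# Returns band-integrated power when `band` is given.
welch_psd <- function(x, fs, nperseg = NULL) {
  n <- length(x)
  nperseg <- min(nperseg %||% 2^floor(log2(n / 4.5)), n)
  nperseg <- max(nperseg, 8L)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.54 - 0.46 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))
  u <- sum(win^2)
  segs <- vapply(starts, function(s) x[s:(s + nperseg - 1L)],
                 numeric(nperseg))
  segs <- (segs - rep(colMeans(segs), each = nperseg)) * win
  sp <- abs(stats::mvfft(segs))^2
  nk <- floor(nperseg / 2) + 1L
  psd <- rowSums(sp[seq_len(nk), , drop = FALSE]) /
    (length(starts) * u * fs)
  # one-sided: double everything but DC and (for even nperseg) Nyquist
  idx <- 2:(length(psd) - as.integer(nperseg %% 2L == 0L))
  psd[idx] <- 2 * psd[idx]
  freq <- (seq_along(psd) - 1L) * fs / nperseg
  list(freq = freq, psd = psd)
}

band_power <- function(welch, lo, hi) {
  sel <- welch$freq >= lo & welch$freq <= hi
  if (!any(sel)) return(0)
  df <- welch$freq[2] - welch$freq[1]
  sum(welch$psd[sel]) * df
}

# Shannon entropy in bits of a count/probability vector.
shannon_entropy <- function(counts) {
  p <- counts[counts > 0]
  if (length(p) == 0L) return(NA_real_)
  p <- p / sum(p)
  -sum(p * log2(p))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}
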