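# Resampling with explicit anti-alias control. When downsampling, a
# low-pass at 0.8 * (fs_new / 2) is applied first; the grid change itself
# is Kaiser-windowed sinc (band-limited) interpolation.

# Windowed-sinc low-pass with cutoff fc_hz; stopband reached at fc_hz / 0.8
# (the new Nyquist when used as an anti-alias filter).
design_antialias_filter <- function(fs, fc_hz, atten_db = 60) {
  df <- 2 * (fc_hz / 0.8 - fc_hz)           # full transition width, Hz
  dw <- 2 * pi * df / fs
  m <- ceiling((atten_db - 7.95) / (2.285 * dw))
  n <- 2L * as.integer(m) + 1L
  beta <- kaiser_beta(atten_db)
  k <- seq_len(n) - 1L - m
  h <- 2 * fc_hz / fs * sinc(2 * fc_hz * k / fs) * signal::kaiser(n, beta)
  h <- h / sum(h)
  attr(h, "fs") <- fs
  attr(h, "delay") <- as.integer(m)
  h
}

# Band-limited interpolation of x at fractional (1-based) positions `pos`.
# Kaiser-windowed sinc kernel; truncated edge kernels are renormalized.
sinc_interp <- function(x, pos, half_width = 36L, beta = 6) {
  n <- length(x)
  i0 <- floor(pos)
  fr <- pos - i0
  y <- numeric(length(pos))
  wsum <- numeric(length(pos))
  for (k in (-half_width + 1L):half_width) {
    idx <- i0 + k
    ok <- idx >= 1L & idx <= n
    u <- fr - k
    w <- sinc(u) * kaiser_val(u / half_width, beta)
    y[ok] <- y[ok] + w[ok] * x[idx[ok]]
    wsum[ok] <- wsum[ok] + w[ok]
  }
  bad <- wsum == 0
  y[!bad] <- y[!bad] / wsum[!bad]
  y
}

#' Resample an ECG record
#'
#' Changes the sampling rate to `fs_new`. When downsampling, an anti-alias
#' low-pass with cutoff `0.8 * (fs_new / 2)` is applied first. Ground-truth
#' apex times (seconds) are carried over unchanged: the truth is a property
#' of the continuous-time signal, not of the grid.
#'
#' @param rec an [ecg_record()].
#' @param fs_new target sampling rate in Hz.
#' @return The resampled [ecg_record()] with `ceiling(n * fs_new / fs)`
#'   samples.
#' @export
resample_ecg <- function(rec, fs_new) {
  if (!is_scalar_number(fs_new) || fs_new <= 0) stop_parameter("fs_new must be positive")
  if (abs(fs_new - rec$fs) < 1e-9 * rec$fs) return(rec)
  x <- rec$samples
  if (fs_new < rec$fs) {
    h <- design_antialias_filter(rec$fs, 0.8 * fs_new / 2)
    x <- apply_fir_centered(h, x)
  }
  n_new <- ceiling(length(x) * fs_new / rec$fs)
  pos <- (seq_len(n_new) - 1) * rec$fs / fs_new + 1
  out <- rec
  out$samples <- sinc_interp(x, pos)
  out$fs <- fs_new
  out
}
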