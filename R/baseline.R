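# Baseline-wander removal: linear-phase FIR high-pass, Kaiser window of
# 1.016 s, 0.8 Hz cutoff, 30 dB side-lobe attenuation. The high-pass is
# built by spectral inversion of a unity-DC-gain windowed-sinc low-pass, so
# the DC gain of the high-pass is exactly zero.

#' Design the baseline-removal high-pass filter
#'
#' Linear-phase FIR high-pass with a Kaiser window spanning `dur_s` seconds,
#' cutoff (half-amplitude point) at `fc_hz` and the given side-lobe
#' attenuation. The filter length is `round(dur_s * fs)` forced odd so the
#' group delay is an integer number of samples.
#'
#' @param fs sampling rate in Hz.
#' @param dur_s window duration in seconds (default 1.016).
#' @param fc_hz cutoff frequency in Hz (default 0.8).
#' @param atten_db side-lobe attenuation in dB (default 30).
#' @return Numeric coefficient vector with attributes `fs` and `delay`
#'   (group delay in samples).
#' @export
design_baseline_filter <- function(fs, dur_s = 1.016, fc_hz = 0.8, atten_db = 30) {
  if (!is_scalar_number(fs) || fs <= 0) stop_parameter("fs must be positive")
  n <- round(dur_s * fs)
  if (n %% 2 == 0) n <- n + 1L
  if (n < 3L) stop_parameter("filter length too short at this sampling rate")
  beta <- kaiser_beta(atten_db)
  k <- seq_len(n) - 1L - (n - 1L) / 2
  h_lp <- 2 * fc_hz / fs * sinc(2 * fc_hz * k / fs) * signal::kaiser(n, beta)
  h_lp <- h_lp / sum(h_lp)            # exact unity DC gain
  h <- -h_lp
  h[(n - 1L) / 2 + 1L] <- h[(n - 1L) / 2 + 1L] + 1   # spectral inversion
  attr(h, "fs") <- fs
  attr(h, "delay") <- (n - 1L) / 2
  h
}

#' Frequency response magnitude of an FIR filter
#'
#' @param h FIR coefficients.
#' @param f_hz frequencies (Hz) at which to evaluate.
#' @param fs sampling rate in Hz (defaults to the `fs` attribute of `h`).
#' @return Magnitude response at each frequency.
#' @export
fir_response <- function(h, f_hz, fs = attr(h, "fs")) {
  k <- seq_along(h) - 1L
  vapply(f_hz, function(f) Mod(sum(h * exp(-2i * pi * f * k / fs))), numeric(1))
}

# FIR filtering with integer group-delay compensation: pad, filter, trim.
apply_fir_centered <- function(h, x) {
  d <- attr(h, "delay")
  y <- signal::fftfilt(as.numeric(h), c(x, numeric(d)))
  y[(d + 1L):(d + length(x))]
}

#' Remove baseline wander from an ECG record
#'
#' Applies the high-pass of [design_baseline_filter()] with the group delay
#' compensated, so the output is aligned with the input and has the same
#' length. The first and last filter length of the output are edge
#' transients; they are flagged in the returned record's `transient_s`
#' field, not removed.
#'
#' @param rec an [ecg_record()], longer than the 1.016 s filter.
#' @inheritParams design_baseline_filter
#' @return The filtered [ecg_record()].
#' @export
remove_baseline <- function(rec, dur_s = 1.016, fc_hz = 0.8, atten_db = 30) {
  h <- design_baseline_filter(rec$fs, dur_s, fc_hz, atten_db)
  if (length(rec$samples) <= length(h))
    stop_length(sprintf("record (%d samples) not longer than the %d-sample filter",
                        length(rec$samples), length(h)))
  out <- rec
  out$samples <- apply_fir_centered(h, rec$samples)
  out$transient_s <- length(h) / rec$fs
  out
}
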