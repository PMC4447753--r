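# Controlled signal degradation: amplitude clipping, additive Gaussian
# noise at a target SNR, and mock false-positive injection.

#' Clip an ECG record
#'
#' Computes the median `p_m` and the 99.9th percentile `p_M` of the
#' amplitude and clips at the threshold `ct = p_m + cf * (p_M - p_m)`. By
#' default clipping is symmetric about the median (the floor is
#' `p_m - cf * (p_M - p_m)`); `mode = "saturate"` clips the top side only.
#' `cf = 1` leaves at most 0.1% of the samples altered on the positive
#' side; `cf = 0.3` is a severe saturation artifact.
#'
#' Note that clipping with a clipping *factor* is not idempotent when more
#' than 0.1% of the samples get clipped: the second application sees a
#' lower 99.9th percentile and clips deeper. To re-apply a realized
#' threshold (which is idempotent), pass the returned `spec` back in.
#'
#' @param rec a baseline-removed [ecg_record()].
#' @param cf clipping factor in (0, 1].
#' @param mode `"symmetric"` (default) or `"saturate"` (one-sided).
#' @param spec optional `clip_spec` from a previous call; reuses its
#'   realized thresholds instead of recomputing them from `rec`.
#' @return List with `record` (the clipped [ecg_record()]) and `spec`
#'   (class `clip_spec`: `cf`, `ct`, `floor`, `p_m`, `p_M`, `mode`,
#'   `n_clipped`).
#' @export
clip_signal <- function(rec, cf, mode = c("symmetric", "saturate"), spec = NULL) {
  s <- rec$samples
  if (!is.null(spec)) {
    cf <- spec$cf; mode <- spec$mode
    p_m <- spec$p_m; p_M <- spec$p_M; ct <- spec$ct; fl <- spec$floor
  } else {
    mode <- match.arg(mode)
    if (!is_scalar_number(cf) || cf <= 0 || cf > 1)
      stop_parameter("cf must be in (0, 1]")
    p_m <- stats::median(s)
    p_M <- stats::quantile(s, 0.999, names = FALSE)  # linear interpolation
    ct <- p_m + cf * (p_M - p_m)
    fl <- if (mode == "symmetric") p_m - cf * (p_M - p_m) else -Inf
  }
  out <- rec
  out$samples <- pmin(pmax(s, fl), ct)
  spec <- structure(list(cf = cf, ct = ct, floor = fl, p_m = p_m, p_M = p_M,
                         mode = mode, n_clipped = sum(s > ct | s < fl)),
                    class = "clip_spec")
  list(record = out, spec = spec)
}

#' Add Gaussian noise at a target SNR
#'
#' Adds zero-mean white Gaussian noise with variance `mean(s^2) /
#' 10^(snr_db / 10)`, treating the noise already present in the signal as
#' negligible. Seeded and reproducible; the caller's RNG stream is left
#' untouched.
#'
#' @param rec an [ecg_record()] with nonzero power.
#' @param snr_db target signal-to-noise ratio in dB.
#' @param seed RNG seed (NULL uses the current stream).
#' @return The noisy [ecg_record()] with attribute `noise_sigma`.
#' @export
add_noise <- function(rec, snr_db, seed = NULL) {
  if (!is_scalar_number(snr_db)) stop_parameter("snr_db must be a number")
  p <- mean(rec$samples^2)
  if (p == 0) stop_parameter("zero-power signal: SNR undefined")
  sigma <- sqrt(p / 10^(snr_db / 10))
  out <- rec
  out$samples <- rec$samples + with_seed(seed, stats::rnorm(length(rec$samples), 0, sigma))
  attr(out, "noise_sigma") <- sigma
  attr(out, "snr_db") <- snr_db
  out
}

#' Inject mock false positives into a detection list
#'
#' Appends `round(f_i / 100 * N)` uniformly distributed random sample
#' indices (so `f_i = 100` doubles the list), re-sorts, and keeps per-index
#' provenance so mock detections remain distinguishable from original
#' ones. Mocks may fall near true beats; the localization stage merges
#' those.
#'
#' @param det a [qrs_detections()].
#' @param f_i mock false-positive percentage (>= 0).
#' @param record_len record length in samples.
#' @param seed RNG seed.
#' @return A [qrs_detections()] with `origin` flags `"detector"`/`"mock"`.
#' @export
inject_false_positives <- function(det, f_i, record_len, seed = NULL) {
  if (!is_scalar_number(f_i) || f_i < 0) stop_parameter("f_i must be >= 0")
  n_mock <- round(f_i / 100 * length(det$indices))
  if (n_mock == 0) return(det)
  mock <- with_seed(seed, sample.int(as.integer(record_len), n_mock, replace = TRUE))
  idx <- c(det$indices, mock)
  org <- c(det$origin, rep("mock", n_mock))
  o <- order(idx)
  qrs_detections(idx[o], det$fs, origin = org[o])
}
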